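# Superpixel Shapley-value attribution: segment the drawing, treat each
# segment as a player whose "absence" replaces its pixels by a baseline,
# and estimate each segment's contribution to the PD posterior.

img_intensity <- function(image) {
  if (length(dim(image)) == 3) apply(image, c(1, 2), mean) else image
}

#' Superpixel segmentation
#'
#' SLIC-style partition: k-means over (row, col, intensity) features with
#' grid-initialized centers (spatial coordinates weighted by the
#' compactness over the expected segment spacing), followed by
#' connectivity enforcement — every final segment is one 4-connected
#' region; disconnected fragments are merged into the neighboring
#' segment they touch most. The realized segment count `S` may differ
#' slightly from `n_segments` and is reported.
#'
#' @param image `H x W` matrix or `H x W x C` array (channels averaged).
#' @param n_segments Requested segment count (>= 1, <= pixel count).
#' @param seed Integer seed.
#' @param compactness Spatial-vs-intensity weighting; larger values give
#'   more regular, squarer segments.
#' @return `H x W` integer matrix of segment ids `0..S-1` with attribute
#'   `n_segments = S`.
#' @export
superpixels <- function(image, n_segments = 60L, seed = 1L,
                        compactness = 0.2) {
  I <- img_intensity(image)
  H <- nrow(I); W <- ncol(I)
  if (n_segments < 1) stopf("n_segments must be >= 1")
  if (n_segments > H * W) stopf("n_segments exceeds the pixel count")
  if (n_segments == 1) {
    seg <- matrix(0L, H, W)
    attr(seg, "n_segments") <- 1L
    return(seg)
  }
  S0 <- sqrt(H * W / n_segments)          # expected segment spacing
  g <- expand.grid(r = seq_len(H), c = seq_len(W))
  feats <- cbind(g$r * compactness / S0, g$c * compactness / S0,
                 as.numeric(I))
  gr <- max(1L, round(sqrt(n_segments * H / W)))
  gc <- max(1L, ceiling(n_segments / gr))
  cr <- round(seq(1, H, length.out = gr + 2))[2:(gr + 1)]
  cc <- round(seq(1, W, length.out = gc + 2))[2:(gc + 1)]
  ctr_idx <- as.numeric(outer(cr, (cc - 1) * H, "+"))[seq_len(n_segments)]
  centers <- feats[ctr_idx, , drop = FALSE]
  centers <- centers[!duplicated(centers), , drop = FALSE]
  km <- with_seed(seed, stats::kmeans(feats, centers = centers,
                                      iter.max = 20L))
  lab <- matrix(km$cluster, H, W)
  lab <- enforce_connectivity(lab)
  ids <- sort(unique(as.integer(lab)))
  seg <- matrix(match(as.integer(lab), ids) - 1L, H, W)
  attr(seg, "n_segments") <- length(ids)
  seg
}

# Keep, per k-means label, its largest 4-connected component; merge every
# other fragment into the adjacent label it touches most.
enforce_connectivity <- function(lab) {
  H <- nrow(lab); W <- ncol(lab)
  for (pass in 1:10) {
    changed <- FALSE
    for (l in unique(as.integer(lab))) {
      comp <- EBImage::bwlabel(lab == l)
      nc <- max(comp)
      if (nc <= 1) next
      sizes <- tabulate(comp[comp > 0], nc)
      keep <- which.max(sizes)
      for (k in setdiff(seq_len(nc), keep)) {
        px <- which(comp == k, arr.ind = TRUE)
        nb <- integer(0)
        for (i in seq_len(nrow(px))) {
          r <- px[i, 1]; c <- px[i, 2]
          if (r > 1 && lab[r - 1, c] != l) nb <- c(nb, lab[r - 1, c])
          if (r < H && lab[r + 1, c] != l) nb <- c(nb, lab[r + 1, c])
          if (c > 1 && lab[r, c - 1] != l) nb <- c(nb, lab[r, c - 1])
          if (c < W && lab[r, c + 1] != l) nb <- c(nb, lab[r, c + 1])
        }
        if (length(nb)) {
          tb <- table(nb)
          lab[comp == k] <- as.integer(names(tb)[which.max(tb)])
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  lab
}

mask_image <- function(image, segments, keep, baseline_value) {
  out <- image
  drop <- !(segments %in% keep)
  if (length(dim(image)) == 3) {
    for (k in seq_len(dim(image)[3])) {
      ch <- out[, , k]
      ch[drop] <- baseline_value[min(k, length(baseline_value))]
      out[, , k] <- ch
    }
  } else out[drop] <- baseline_value[1]
  out
}

shapley_weights <- function(S) {
  # weight of a coalition of size s (excluding player i): s!(S-s-1)!/S!
  lf <- lgamma(seq_len(S + 1))            # lf[k+1] = log(k!)
  exp(lf[seq(0, S - 1) + 1] + lf[S - seq(0, S - 1)] - lf[S + 1])
}

#' Shapley-value attribution over superpixels
#'
#' The value of a coalition `T` is the model output on the image with
#' every segment outside `T` replaced by the baseline. `exact` mode
#' enumerates all `2^S` coalitions (S <= 14) and applies the Shapley
#' formula, guaranteeing the efficiency axiom; `sampled` mode fits the
#' Kernel-SHAP weighted regression on `n_samples` seeded coalitions,
#' always anchoring the empty and full coalitions.
#'
#' @param model_fn Function mapping an image to a scalar (the PD
#'   posterior).
#' @param image The input image (matrix or `H x W x C` array).
#' @param segments Segment-id matrix from [superpixels()].
#' @param baseline `"zero"` (blank paper) or `"mean"` (per-channel mean).
#' @param mode `"exact"` or `"sampled"`.
#' @param n_samples Sampled-mode coalition count.
#' @param seed Integer seed (sampled mode).
#' @return List `phi` (per-segment Shapley values), `f_x`, `f_baseline`,
#'   `mode`, `seed`, `n_segments`.
#' @export
shapley_attribution <- function(model_fn, image, segments,
                                baseline = c("zero", "mean"),
                                mode = c("exact", "sampled"),
                                n_samples = 2000L, seed = 1L) {
  baseline <- match.arg(baseline)
  mode <- match.arg(mode)
  S <- attr(segments, "n_segments") %||% (max(segments) + 1L)
  base_val <- if (baseline == "zero") 0 else {
    if (length(dim(image)) == 3) apply(image, 3, mean) else mean(image)
  }
  v_of <- function(members) {   # members: logical length S over ids 0..S-1
    model_fn(mask_image(image, segments, which(members) - 1L, base_val))
  }
  if (mode == "exact") {
    if (S > 14) stopf("exact mode supports at most 14 segments (got %d)", S)
    nT <- bitwShiftL(1L, S)
    vals <- numeric(nT)
    bits <- matrix(FALSE, nT, S)
    for (t in seq_len(nT) - 1L) {
      mem <- bitwAnd(bitwShiftR(t, seq_len(S) - 1L), 1L) == 1L
      bits[t + 1L, ] <- mem
      vals[t + 1L] <- v_of(mem)
    }
    wt <- shapley_weights(S)
    phi <- numeric(S)
    sizes <- rowSums(bits)
    for (i in seq_len(S)) {
      without <- which(!bits[, i])
      with_i <- without + bitwShiftL(1L, i - 1L)
      phi[i] <- sum(wt[sizes[without] + 1L] * (vals[with_i] - vals[without]))
    }
    f_base <- vals[1]; f_x <- vals[nT]
  } else {
    with_seed(seed, {
      ks <- seq_len(S - 1)
      kw <- (S - 1) / (choose(S, ks) * ks * (S - ks))
      Z <- matrix(FALSE, n_samples, S)
      sz <- sample(ks, n_samples, replace = TRUE, prob = kw * choose(S, ks))
      for (j in seq_len(n_samples)) Z[j, sample.int(S, sz[j])] <- TRUE
      v <- apply(Z, 1, v_of)
      w <- (S - 1) / (choose(S, sz) * sz * (S - sz))
      f_base <- v_of(rep(FALSE, S)); f_x <- v_of(rep(TRUE, S))
      Z <- rbind(rep(FALSE, S), rep(TRUE, S), Z)
      v <- c(f_base, f_x, v)
      w <- c(1e6, 1e6, w)
      fit <- stats::lm.wfit(cbind(1, Z * 1), v, w)
      phi <- unname(fit$coefficients[-1])
      phi[is.na(phi)] <- 0
    })
  }
  list(phi = phi, f_x = f_x, f_baseline = f_base, mode = mode, seed = seed,
       n_segments = S)
}

#' Render an attribution overlay
#'
#' Symmetric diverging color scale centred at zero with extremes at
#' +/- max |phi|: warm colors mark segments pushing toward the PD
#' prediction, cool colors segments opposing it; zero attributions are
#' neutral. The drawing itself is blended on top.
#'
#' @param image Input image (matrix or array).
#' @param phi Per-segment Shapley values.
#' @param segments Segment-id matrix.
#' @param blend Weight of the drawing in the blend.
#' @return `H x W x 3` RGB array in \[0, 1\].
#' @export
render_map <- function(image, phi, segments, blend = 0.5) {
  I <- img_intensity(image)
  H <- nrow(I); W <- ncol(I)
  pal <- grDevices::colorRampPalette(c("#2166AC", "#F7F7F7", "#B2182B"))(255)
  m <- max(abs(phi))
  sc <- if (m > 0) phi / m else phi * 0
  idx <- pmin(pmax(round((sc + 1) / 2 * 254) + 1, 1), 255)
  colmat <- grDevices::col2rgb(pal[idx[segments + 1L]]) / 255
  out <- array(0, c(H, W, 3))
  for (k in 1:3)
    out[, , k] <- (1 - blend) * matrix(colmat[k, ], H, W) + blend * I
  pmin(pmax(out, 0), 1)
}

#' Model predictor for attribution
#'
#' Wraps a trained model as the scalar function (PD posterior) consumed
#' by [shapley_attribution()].
#'
#' @param model A `spiralnet_model`.
#' @return Function `image -> p_pd`.
#' @export
model_predictor <- function(model) {
  function(image) predict_proba(model, list(image))[1, 1]
}
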