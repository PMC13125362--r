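#' Remove impulse noise from a drawing image
#'
#' Impulse/speckle artifacts form tiny connected components; removing
#' components below `min_size` pixels (8-connectivity) eliminates them
#' without eroding thin strokes. An optional 3x3 median filter is
#' available for heavier salt-and-pepper noise, off by default because a
#' plain median erases 1-2 px wide strokes.
#'
#' @param image Intensity matrix in \[0, 1\].
#' @param min_size Minimum connected-component size kept, in pixels.
#' @param median Apply a 3x3 median filter first.
#' @return Denoised intensity matrix, range preserved in \[0, 1\].
#' @export
denoise <- function(image, min_size = 5L, median = FALSE) {
  if (length(image) == 0) stopf("empty image")
  if (median) image <- EBImage::medianFilter(image, 1L)
  ink <- image > 0
  if (any(ink) && min_size > 1) {
    lab <- EBImage::bwlabel(ink)
    sizes <- tabulate(lab[lab > 0])
    drop <- which(sizes < min_size)
    if (length(drop)) image[lab %in% drop] <- 0
  }
  pmin(pmax(image, 0), 1)
}

#' Segment the inked region by Otsu thresholding
#'
#' Computes the global threshold maximizing between-class variance over
#' 256 intensity bins and returns the binary ink mask.
#'
#' @param image Intensity matrix in \[0, 1\] with intensity variation.
#' @return Binary matrix (1 = ink) of the same dimensions, with the
#'   threshold in attribute `threshold`.
#' @export
segment_ink <- function(image) {
  if (diff(range(image)) == 0)
    stopf("no ink: image has no intensity variation")
  th <- EBImage::otsu(image, range = c(0, 1), levels = 256)
  mask <- (image > th) * 1
  if (!any(mask == 1)) stopf("no ink above the Otsu threshold")
  attr(mask, "threshold") <- th
  mask
}

#' Tight bounding box of the ink mask
#'
#' Returns the tightest half-open box (0-based, `[start, end)` on both
#' axes) containing all ink, expanded by `margin` and clipped to the
#' image bounds.
#'
#' @param mask Binary ink mask with at least one ink pixel.
#' @param margin Non-negative integer margin in pixels.
#' @return List `row_start`, `row_end`, `col_start`, `col_end`.
#' @export
crop_to_content <- function(mask, margin = 0L) {
  if (margin < 0) stopf("margin must be >= 0")
  w <- which(mask > 0, arr.ind = TRUE)
  if (nrow(w) == 0) stopf("no ink: empty mask")
  list(row_start = max(min(w[, 1]) - 1L - margin, 0L),
       row_end   = min(max(w[, 1]) + margin, nrow(mask)),
       col_start = max(min(w[, 2]) - 1L - margin, 0L),
       col_end   = min(max(w[, 2]) + margin, ncol(mask)))
}

crop_apply <- function(image, bbox) {
  image[(bbox$row_start + 1L):bbox$row_end,
        (bbox$col_start + 1L):bbox$col_end, drop = FALSE]
}

# Inverse-map affine warp: output pixel (r, c) samples the input at
# M %*% (out - out_center) + in_center, bilinearly, background 0.
warp_affine <- function(image, M, in_center, out_dim,
                        out_center = (out_dim + 1) / 2) {
  H <- nrow(image); W <- ncol(image)
  g <- expand.grid(r = seq_len(out_dim[1]), c = seq_len(out_dim[2]))
  dr <- g$r - out_center[1]; dc <- g$c - out_center[2]
  rin <- M[1, 1] * dr + M[1, 2] * dc + in_center[1]
  cin <- M[2, 1] * dr + M[2, 2] * dc + in_center[2]
  s <- cpp_bilinear(as.numeric(image), H, W, 1L, rin - 1, cin - 1)
  matrix(s[, 1], out_dim[1], out_dim[2])
}

resize_bilinear <- function(image, h, w) {
  H <- nrow(image); W <- ncol(image)
  g <- expand.grid(r = seq_len(h), c = seq_len(w))
  rin <- (g$r - 0.5) * H / h - 0.5
  cin <- (g$c - 0.5) * W / w - 0.5
  s <- cpp_bilinear(as.numeric(image), H, W, 1L, rin, cin)
  matrix(s[, 1], h, w)
}

# Principal-axis angle (radians, vs. the horizontal/column axis) and
# eigenvalue ratio of the ink second-moment matrix.
ink_axis <- function(mask) {
  w <- which(mask > 0, arr.ind = TRUE)
  if (nrow(w) < 2) return(list(angle = 0, ratio = 1))
  cv <- stats::cov(w)
  e <- eigen(cv, symmetric = TRUE)
  v <- e$vectors[, 1]
  ratio <- e$values[1] / max(e$values[2], 1e-12)
  ang <- atan2(v[1], v[2])              # (row, col) components
  if (ang > pi / 2) ang <- ang - pi     # fold to (-pi/2, pi/2]
  if (ang <= -pi / 2) ang <- ang + pi
  list(angle = ang, ratio = ratio)
}

#' Scale and rotation normalization
#'
#' Rotates the drawing so the principal axis of the ink's second-moment
#' matrix is horizontal (applied only when the eigenvalue ratio exceeds
#' `rotate_threshold`, since near-isotropic spirals have no meaningful
#' principal axis), then isotropically rescales the content so its longer
#' side fills `fill_fraction` of the canvas, and centres it. Output
#' dimensions equal input dimensions. Degenerate (single-pixel) content
#' is centred without scaling.
#'
#' @param image Segmented, cropped intensity matrix in \[0, 1\].
#' @param fill_fraction Target fraction of the shorter canvas side.
#' @param rotate_threshold Minimum second-moment eigenvalue ratio for the
#'   rotation step to be applied.
#' @return Normalized intensity matrix of the same dimensions.
#' @export
normalize_geometry <- function(image, fill_fraction = 0.9,
                               rotate_threshold = 1.2) {
  H <- nrow(image); W <- ncol(image)
  mask <- image > max(image) / 2
  if (!any(mask)) return(image)
  ax <- ink_axis(mask)
  if (ax$ratio > rotate_threshold && abs(ax$angle) > 1e-4) {
    ctr <- colMeans(which(mask, arr.ind = TRUE))
    cs <- cos(ax$angle); sn <- sin(ax$angle)
    # output frame axis-aligned; inverse map rotates back by +angle
    M <- matrix(c(cs, sn, -sn, cs), 2, 2, byrow = TRUE)
    image <- warp_affine(image, M, ctr, c(H, W))
    mask <- image > max(image) / 2
    if (!any(mask)) return(pmin(pmax(image, 0), 1))
  }
  w <- which(mask, arr.ind = TRUE)
  bh <- diff(range(w[, 1])) + 1L; bw <- diff(range(w[, 2])) + 1L
  ctr <- c(mean(range(w[, 1])), mean(range(w[, 2])))
  long <- max(bh, bw)
  if (long > 1) {
    s <- fill_fraction * min(H, W) / long
    M <- diag(2) / s
    image <- warp_affine(image, M, ctr, c(H, W))
  } else {
    M <- diag(2)
    image <- warp_affine(image, M, ctr, c(H, W))
  }
  pmin(pmax(image, 0), 1)
}

#' Standardize one raw drawing
#'
#' Full single-image pipeline: denoise, segment ink, crop to content with
#' a margin, place on a square canvas, and normalize scale/rotation.
#'
#' @param image Raw intensity matrix in \[0, 1\].
#' @param margin Crop margin in pixels.
#' @param ... Passed to [normalize_geometry()].
#' @return Standardized square intensity matrix.
#' @export
preprocess_drawing <- function(image, margin = 4L, ...) {
  d <- denoise(image)
  m <- segment_ink(d)
  bb <- crop_to_content(m, margin)
  cropped <- crop_apply(d, bb)
  side <- max(nrow(cropped), ncol(cropped))
  canvas <- matrix(0, side, side)
  r0 <- floor((side - nrow(cropped)) / 2)
  c0 <- floor((side - ncol(cropped)) / 2)
  canvas[r0 + seq_len(nrow(cropped)), c0 + seq_len(ncol(cropped))] <- cropped
  normalize_geometry(canvas, ...)
}

sobel_magnitude <- function(image) {
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3)
  gx <- EBImage::filter2(image, kx)
  gy <- EBImage::filter2(image, t(kx))
  g <- sqrt(gx^2 + gy^2)
  m <- max(g)
  if (m > 0) g / m else g
}

#' Fuse drawings into the model's RGB input
#'
#' In `multitask` mode the three channels are the subject's spiral,
#' meander, and wave drawings (in that order), each resized to
#' `size` x `size`. In `single_filtered` mode the channels are the raw,
#' edge-enhanced (Sobel magnitude), and Gaussian-smoothed variants of one
#' drawing. The output is always `size` x `size` x 3 with values in
#' \[0, 1\].
#'
#' @param task_images Named list of standardized intensity matrices;
#'   `multitask` mode requires entries `spiral`, `meander`, `wave`.
#' @param mode `"multitask"` or `"single_filtered"`.
#' @param size Output spatial size (default 256).
#' @return `size` x `size` x 3 array with attribute `channels`.
#' @export
fuse_to_rgb <- function(task_images, mode = c("multitask", "single_filtered"),
                        size = 256L) {
  mode <- match.arg(mode)
  if (length(task_images) == 0) stopf("task_images must be non-empty")
  if (mode == "multitask") {
    need <- task_kinds()
    miss <- setdiff(need, names(task_images))
    if (length(miss)) stopf("missing task(s): %s", paste(miss, collapse = ", "))
    chans <- lapply(need, function(t) resize_bilinear(task_images[[t]], size, size))
    labels <- need
  } else {
    raw <- resize_bilinear(task_images[[1]], size, size)
    chans <- list(raw, sobel_magnitude(raw),
                  EBImage::gblur(raw, sigma = 1))
    labels <- c("raw", "edge", "smooth")
  }
  out <- array(0, dim = c(size, size, 3))
  for (k in 1:3) out[, , k] <- pmin(pmax(chans[[k]], 0), 1)
  attr(out, "channels") <- labels
  out
}

#' Preprocess a cohort manifest into fused model inputs
#'
#' Loads each drawing (from disk or from the manifest's in-memory
#' images), standardizes it, and fuses per subject (`multitask`) or per
#' drawing (`single_filtered`).
#'
#' @param manifest Cohort manifest from [synthesize_cohort()] (or a data
#'   frame with columns `subject_id`, `label`, `task`, `path`).
#' @param mode Channel composition policy, see [fuse_to_rgb()].
#' @param size Fused input spatial size.
#' @param margin Crop margin, see [preprocess_drawing()].
#' @return List with `inputs` (list of `size` x `size` x 3 arrays),
#'   `labels`, and `subject_ids`, aligned.
#' @export
preprocess_cohort <- function(manifest, mode = "multitask", size = 256L,
                              margin = 4L) {
  images <- attr(manifest, "images")
  load_img <- function(row) {
    key <- paste0(manifest$subject_id[row], "_", manifest$task[row])
    if (!is.null(images)) images[[key]] else read_drawing_png(manifest$path[row])
  }
  inputs <- list(); labels <- integer(0); sids <- character(0)
  if (mode == "multitask") {
    for (sid in unique(manifest$subject_id)) {
      rows <- which(manifest$subject_id == sid)
      ims <- lapply(rows, function(r) preprocess_drawing(load_img(r), margin))
      names(ims) <- manifest$task[rows]
      inputs[[length(inputs) + 1L]] <- fuse_to_rgb(ims, "multitask", size)
      labels <- c(labels, manifest$label[rows[1]])
      sids <- c(sids, sid)
    }
  } else {
    for (r in seq_len(nrow(manifest))) {
      im <- preprocess_drawing(load_img(r), margin)
      inputs[[length(inputs) + 1L]] <-
        fuse_to_rgb(stats::setNames(list(im), manifest$task[r]),
                    "single_filtered", size)
      labels <- c(labels, manifest$label[r])
      sids <- c(sids, manifest$subject_id[r])
    }
  }
  list(inputs = inputs, labels = labels, subject_ids = sids)
}
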