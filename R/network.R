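#' Model configuration
#'
#' Describes the complete architecture: a five-stage backbone of
#' stride-1 "same" convolutions (each stage: entry convolution +
#' depthwise-separable convolution, each followed by optional batch
#' normalization and a nonlinear activation, then 2x2 max-pooling), three
#' attention branches drawn from intermediate stages, the gated
#' multi-head attention fusion, channel reduction, global average
#' pooling, and the 2-class softmax head (class 1 = PD, class 2 =
#' healthy). The entry convolutions of stages 3-5 are standard (dense)
#' convolutions; all other convolutions are depthwise separable.
#'
#' @param input_size Input spatial size (square), default 256.
#' @param in_channels Input channels, default 3.
#' @param filters Filter counts per stage, default `c(64, 128, 256, 512, 512)`.
#' @param kernel Convolution kernel size, default 3.
#' @param batch_norm Use batch normalization after each convolution.
#' @param activation `"relu"` (default) or `"tanh"`; also used for the
#'   gating network and the channel-reduction block.
#' @param branch_stages Backbone stages feeding the three attention
#'   branches (fine, medium, coarse), default `c(3, 4, 5)`.
#' @param d Attention embedding dimension, default 192.
#' @param heads Attention heads (must divide `d`), default 4.
#' @param pool_hw Projected spatial size of each branch, default 7
#'   (7 x 7 = 49 tokens).
#' @param reduce_dim Channel-reduced depth before global average pooling,
#'   default 32.
#' @param gate_hidden Hidden width of the shared gating network.
#' @param dropout Dropout rate applied after the fusion block during
#'   training, default 0.3.
#' @param n_classes Number of classes (2).
#' @return A `dscnn_config` list.
#' @export
dscnn_config <- function(input_size = 256L, in_channels = 3L,
                         filters = c(64L, 128L, 256L, 512L, 512L),
                         kernel = 3L, batch_norm = TRUE,
                         activation = c("relu", "tanh"),
                         branch_stages = c(3L, 4L, 5L), d = 192L,
                         heads = 4L, pool_hw = 7L, reduce_dim = 32L,
                         gate_hidden = 32L, dropout = 0.3,
                         n_classes = 2L) {
  activation <- match.arg(activation)
  if (length(filters) != 5) stopf("exactly 5 backbone stages are required")
  if (d %% heads != 0) stopf("heads must divide d")
  if (length(branch_stages) != 3) stopf("exactly 3 branch stages")
  sizes <- input_size / 2^(1:5)
  if (any(sizes[branch_stages] < pool_hw))
    stopf("branch source maps smaller than the projected size %d", pool_hw)
  structure(list(input_size = as.integer(input_size),
                 in_channels = as.integer(in_channels),
                 filters = as.integer(filters), kernel = as.integer(kernel),
                 batch_norm = isTRUE(batch_norm), activation = activation,
                 branch_stages = as.integer(branch_stages), d = as.integer(d),
                 heads = as.integer(heads), pool_hw = as.integer(pool_hw),
                 reduce_dim = as.integer(reduce_dim),
                 gate_hidden = as.integer(gate_hidden), dropout = dropout,
                 n_classes = as.integer(n_classes),
                 entry_standard = c(FALSE, FALSE, TRUE, TRUE, TRUE)),
            class = "dscnn_config")
}

#' Analytic trainable-parameter count
#'
#' Counts every trainable entry of a model built from `config`, by
#' parameter group. A standard convolution contributes `K^2*M*N + N`
#' entries, a depthwise-separable one `K^2*M + M*N + N`; batch-norm
#' scale/shift, branch projections, attention projections, the shared
#' gate, the channel reduction, and the dense head are itemized.
#'
#' @param config A [dscnn_config()].
#' @return Integer total with attribute `breakdown` (named vector).
#' @export
count_parameters <- function(config) {
  K <- config$kernel; d <- config$d
  bn <- function(n) if (config$batch_norm) 2 * n else 0
  backbone <- 0
  M <- config$in_channels
  for (l in 1:5) {
    Fl <- config$filters[l]
    backbone <- backbone +
      (if (config$entry_standard[l]) K^2 * M * Fl + Fl
       else K^2 * M + M * Fl + Fl) + bn(Fl) +
      K^2 * Fl + Fl * Fl + Fl + bn(Fl)
    M <- Fl
  }
  src <- config$filters[config$branch_stages]
  branches <- sum(src * d + d)
  attn <- 3 * 4 * (d^2 + d)
  gate <- config$gate_hidden * d + 2 * config$gate_hidden
  reduce <- 3 * d * config$reduce_dim + config$reduce_dim
  head <- config$n_classes * config$reduce_dim + config$n_classes
  parts <- c(backbone = backbone, branches = branches, attention = attn,
             gate = gate, reduce = reduce, head = head)
  structure(as.integer(sum(parts)), breakdown = parts)
}

init_conv <- function(config, l, seed_unused = NULL) {
  K <- config$kernel
  M <- if (l == 1) config$in_channels else config$filters[l - 1]
  Fl <- config$filters[l]
  b1 <- if (config$entry_standard[l])
    list(w = he_init(c(K, K, M, Fl), K^2 * M), bias = numeric(Fl))
  else
    list(dw = he_init(c(K, K, M), K^2), pw = he_init(c(M, Fl), M),
         bias = numeric(Fl))
  b2 <- list(dw = he_init(c(K, K, Fl), K^2), pw = he_init(c(Fl, Fl), Fl),
             bias = numeric(Fl))
  if (config$batch_norm) {
    b1$bn <- list(gamma = rep(1, Fl), beta = numeric(Fl))
    b2$bn <- list(gamma = rep(1, Fl), beta = numeric(Fl))
  }
  list(b1 = b1, b2 = b2)
}

#' Initialize a model
#'
#' He-normal initialization of all parameter groups; batch-norm running
#' statistics start at mean 0 / variance 1.
#'
#' @param config A [dscnn_config()].
#' @param seed Integer seed.
#' @return A `spiralnet_model` list with elements `config`, `params`,
#'   `state`.
#' @export
model_init <- function(config, seed = 1L) {
  with_seed(seed, {
    d <- config$d
    params <- list(
      stages = lapply(1:5, function(l) init_conv(config, l)),
      branches = lapply(1:3, function(b) {
        M <- config$filters[config$branch_stages[b]]
        list(pw = he_init(c(M, d), M), bias = numeric(d))
      }),
      attn = lapply(1:3, function(b) list(
        Wq = he_init(c(d, d), d), bq = numeric(d),
        Wk = he_init(c(d, d), d), bk = numeric(d),
        Wv = he_init(c(d, d), d), bv = numeric(d),
        Wo = he_init(c(d, d), d), bo = numeric(d))),
      gate = list(Wg = he_init(c(config$gate_hidden, d), d),
                  bg = numeric(config$gate_hidden),
                  wg = he_init(c(config$gate_hidden), config$gate_hidden)),
      reduce = list(pw = he_init(c(3 * d, config$reduce_dim), 3 * d),
                    bias = numeric(config$reduce_dim)),
      head = list(W = he_init(c(config$n_classes, config$reduce_dim),
                              config$reduce_dim),
                  b = numeric(config$n_classes)))
    state <- list(stages = lapply(1:5, function(l) {
      Fl <- config$filters[l]
      list(b1 = list(mean = numeric(Fl), var = rep(1, Fl)),
           b2 = list(mean = numeric(Fl), var = rep(1, Fl)))
    }))
    structure(list(config = config, params = params, state = state),
              class = "spiralnet_model")
  })
}

flatten_params <- function(p) unlist(p, use.names = FALSE)

unflatten_params <- function(vec, skel) {
  pos <- 0L
  walk <- function(node) {
    if (is.list(node)) return(lapply(node, walk))
    n <- length(node)
    out <- vec[pos + seq_len(n)]
    pos <<- pos + n
    attributes(out) <- attributes(node)
    out
  }
  walk(skel)
}

# 1 where decoupled weight decay applies (conv kernels, projection and
# dense weights), 0 for biases and batch-norm scale/shift.
decay_mask <- function(params) {
  walk <- function(node, name) {
    if (is.list(node))
      return(unlist(mapply(walk, node, names(node) %||% rep("", length(node)),
                           SIMPLIFY = FALSE), use.names = FALSE))
    rep(if (name %in% c("w", "dw", "pw", "Wq", "Wk", "Wv", "Wo", "W", "Wg", "wg"))
      1 else 0, length(node))
  }
  walk(params, "")
}

# ---- forward / backward ----------------------------------------------

# Full-batch forward. Returns probabilities plus (optionally) all caches
# needed by model_backward, and the updated batch-norm state.
model_forward <- function(model, xs, training = FALSE, keep_cache = FALSE,
                          drop_mask = NULL, bn_momentum = 0.9) {
  cfg <- model$config; p <- model$params; st <- model$state
  n <- length(xs)
  act <- cfg$activation
  cache <- list(stages = vector("list", 5))
  branch_src <- vector("list", 3)
  cur <- xs
  for (l in 1:5) {
    sp <- p$stages[[l]]
    cc <- list()
    cv1 <- lapply(cur, function(x)
      if (cfg$entry_standard[l]) conv_std_fwd(x, sp$b1$w, sp$b1$bias)
      else sep_fwd(x, sp$b1$dw, sp$b1$pw, sp$b1$bias))
    ys <- lapply(cv1, `[[`, "y")
    if (cfg$batch_norm) {
      bn1 <- bn_fwd(ys, sp$b1$bn$gamma, sp$b1$bn$beta, training,
                    st$stages[[l]]$b1$mean, st$stages[[l]]$b1$var,
                    momentum = bn_momentum)
      st$stages[[l]]$b1$mean <- bn1$rmean; st$stages[[l]]$b1$var <- bn1$rvar
      pre1 <- bn1$ys
    } else { bn1 <- NULL; pre1 <- ys }
    a1 <- lapply(pre1, act_fwd, kind = act)
    cv2 <- lapply(a1, function(x) sep_fwd(x, sp$b2$dw, sp$b2$pw, sp$b2$bias))
    ys2 <- lapply(cv2, `[[`, "y")
    if (cfg$batch_norm) {
      bn2 <- bn_fwd(ys2, sp$b2$bn$gamma, sp$b2$bn$beta, training,
                    st$stages[[l]]$b2$mean, st$stages[[l]]$b2$var,
                    momentum = bn_momentum)
      st$stages[[l]]$b2$mean <- bn2$rmean; st$stages[[l]]$b2$var <- bn2$rvar
      pre2 <- bn2$ys
    } else { bn2 <- NULL; pre2 <- ys2 }
    a2 <- lapply(pre2, act_fwd, kind = act)
    pl <- lapply(a2, pool_fwd)
    out <- lapply(pl, `[[`, "y")
    if (keep_cache)
      cache$stages[[l]] <- list(cv1 = cv1, bn1 = bn1, pre1 = pre1, a1 = a1,
                                cv2 = cv2, bn2 = bn2, pre2 = pre2, a2 = a2,
                                pl = pl)
    b <- match(l, cfg$branch_stages)
    if (!is.na(b)) branch_src[[b]] <- out
    cur <- out
  }
  # branches: projection -> tokens -> attention
  L <- cfg$pool_hw^2
  tok <- lapply(1:3, function(b) vector("list", n))
  proj_cache <- lapply(1:3, function(b) vector("list", n))
  attn_cache <- lapply(1:3, function(b) vector("list", n))
  for (b in 1:3) {
    bp <- p$branches[[b]]
    for (i in seq_len(n)) {
      x <- branch_src[[b]][[i]]
      dd <- dims3(x)
      zm <- sweep(matrix(x, dd[1] * dd[2], dd[3]) %*% bp$pw, 2, bp$bias, "+")
      z <- array(zm, c(dd[1], dd[2], cfg$d))
      ap <- adapool_fwd(z, cfg$pool_hw)
      X <- matrix(ap$y, L, cfg$d)
      mh <- mha_fwd(X, p$attn[[b]], cfg$heads)
      proj_cache[[b]][[i]] <- list(d_in = dd, ap = ap)
      attn_cache[[b]][[i]] <- mh
      tok[[b]][[i]] <- mh$Y
    }
  }
  # gating, fusion, reduction, GAP, dropout, head
  probs <- matrix(0, n, cfg$n_classes)
  logits <- matrix(0, n, cfg$n_classes)
  alphas <- matrix(0, n, 3)
  fuse_cache <- vector("list", n)
  for (i in seq_len(n)) {
    Ts <- lapply(1:3, function(b) tok[[b]][[i]])
    gw <- gate_forward(Ts, p$gate, act)
    Fcat <- do.call(cbind, lapply(1:3, function(b) gw$alpha[b] * Ts[[b]]))
    pre <- sweep(Fcat %*% p$reduce$pw, 2, p$reduce$bias, "+")
    R <- act_fwd(pre, act)
    z <- colMeans(R)
    if (training && cfg$dropout > 0) {
      mask <- if (is.null(drop_mask)) (stats::runif(length(z)) >= cfg$dropout) /
        (1 - cfg$dropout) else drop_mask[[i]]
      zd <- z * mask
    } else { mask <- NULL; zd <- z }
    s <- as.numeric(p$head$W %*% zd + p$head$b)
    probs[i, ] <- softmax(s)
    logits[i, ] <- s
    alphas[i, ] <- gw$alpha
    fuse_cache[[i]] <- list(Ts = Ts, gw = gw, Fcat = Fcat, pre = pre, R = R,
                            z = z, mask = mask, zd = zd)
  }
  list(probs = probs, logits = logits, alphas = alphas, state = st,
       cache = if (keep_cache) list(stages = cache$stages, proj = proj_cache,
                                    attn = attn_cache, fuse = fuse_cache,
                                    n = n) else NULL)
}

gate_forward <- function(Ts, gp, act) {
  us <- lapply(Ts, colMeans)
  hs <- lapply(us, function(u) act_fwd(as.numeric(gp$Wg %*% u + gp$bg), act))
  scores <- vapply(hs, function(h) sum(gp$wg * h), 0)
  list(us = us, hs = hs, scores = scores, alpha = softmax(scores))
}

zero_like <- function(p) {
  if (is.list(p)) lapply(p, zero_like)
  else { z <- p; z[] <- 0; z }
}

acc_add <- function(a, b) {
  if (is.list(a)) return(mapply(acc_add, a, b, SIMPLIFY = FALSE))
  a + b
}

# Backward pass of the mean cross-entropy loss over the batch.
# Returns gradients shaped like model$params.
model_backward <- function(model, fwd, labels) {
  cfg <- model$config; p <- model$params; ch <- fwd$cache
  n <- ch$n; act <- cfg$activation; L <- cfg$pool_hw^2
  g <- zero_like(p)
  # target class index: label 1 (PD) -> class 1, label 0 -> class 2
  tgt <- ifelse(labels == 1, 1L, 2L)
  gtok <- lapply(1:3, function(b) vector("list", n))
  for (i in seq_len(n)) {
    fc <- ch$fuse[[i]]
    gs <- fwd$probs[i, ]
    gs[tgt[i]] <- gs[tgt[i]] - 1
    gs <- gs / n
    g$head$W <- g$head$W + outer(gs, fc$zd)
    g$head$b <- g$head$b + gs
    gzd <- as.numeric(crossprod(p$head$W, gs))
    gz <- if (!is.null(fc$mask)) gzd * fc$mask else gzd
    gR <- matrix(rep(gz / L, each = L), L, length(gz))
    gpre <- act_bwd(fc$pre, fc$R, gR, act)
    g$reduce$pw <- g$reduce$pw + crossprod(fc$Fcat, gpre)
    g$reduce$bias <- g$reduce$bias + colSums(gpre)
    gFcat <- tcrossprod(gpre, p$reduce$pw)
    d <- cfg$d
    galpha <- numeric(3)
    gT <- vector("list", 3)
    for (b in 1:3) {
      blk <- gFcat[, (b - 1) * d + seq_len(d), drop = FALSE]
      galpha[b] <- sum(blk * fc$Ts[[b]])
      gT[[b]] <- fc$gw$alpha[b] * blk
    }
    # softmax gate backward
    al <- fc$gw$alpha
    gscore <- al * (galpha - sum(galpha * al))
    for (b in 1:3) {
      hb <- fc$gw$hs[[b]]
      g$gate$wg <- g$gate$wg + gscore[b] * hb
      gh <- gscore[b] * p$gate$wg
      preh <- as.numeric(p$gate$Wg %*% fc$gw$us[[b]] + p$gate$bg)
      gpreh <- act_bwd(preh, hb, gh, act)
      g$gate$Wg <- g$gate$Wg + outer(gpreh, fc$gw$us[[b]])
      g$gate$bg <- g$gate$bg + gpreh
      gu <- as.numeric(crossprod(p$gate$Wg, gpreh))
      gT[[b]] <- gT[[b]] + matrix(rep(gu / L, each = L), L, d)
    }
    for (b in 1:3) gtok[[b]][[i]] <- gT[[b]]
  }
  # attention + projection backward, accumulating into stage-output grads
  gstage_out <- list()
  for (l in 1:5) gstage_out[[l]] <- NULL
  gbranch_src <- lapply(1:3, function(b) vector("list", n))
  for (b in 1:3) {
    for (i in seq_len(n)) {
      mb <- mha_bwd(ch$attn[[b]][[i]], p$attn[[b]], gtok[[b]][[i]])
      for (nm in c("Wq", "bq", "Wk", "bk", "Wv", "bv", "Wo", "bo"))
        g$attn[[b]][[nm]] <- g$attn[[b]][[nm]] + mb[[paste0("g", nm)]]
      pc <- ch$proj[[b]][[i]]
      gZ <- adapool_bwd(pc$ap, array(mb$gX, c(cfg$pool_hw, cfg$pool_hw, cfg$d)))
      dd <- pc$d_in
      gzm <- matrix(gZ, dd[1] * dd[2], cfg$d)
      xm <- matrix(ch$stages[[cfg$branch_stages[b]]]$pl[[i]]$y, dd[1] * dd[2],
                   dd[3])
      g$branches[[b]]$pw <- g$branches[[b]]$pw + crossprod(xm, gzm)
      g$branches[[b]]$bias <- g$branches[[b]]$bias + colSums(gzm)
      gbranch_src[[b]][[i]] <- array(tcrossprod(gzm, p$branches[[b]]$pw), dd)
    }
  }
  # backbone backward, stage 5 down to 1
  gcur <- NULL
  for (l in 5:1) {
    sc <- ch$stages[[l]]
    sp <- p$stages[[l]]
    b <- match(l, cfg$branch_stages)
    gout <- vector("list", n)
    for (i in seq_len(n)) {
      gi <- if (is.null(gcur)) array(0, dim(sc$pl[[i]]$y)) else gcur[[i]]
      if (!is.na(b)) gi <- gi + gbranch_src[[b]][[i]]
      gout[[i]] <- gi
    }
    gpool <- lapply(seq_len(n), function(i) pool_bwd(sc$pl[[i]], gout[[i]]))
    ga2 <- lapply(seq_len(n), function(i)
      act_bwd(sc$pre2[[i]], sc$a2[[i]], gpool[[i]], act))
    if (cfg$batch_norm) {
      bb <- bn_bwd(sc$bn2, sp$b2$bn$gamma, ga2)
      g$stages[[l]]$b2$bn$gamma <- bb$ggamma
      g$stages[[l]]$b2$bn$beta <- bb$gbeta
      gy2 <- bb$gxs
    } else gy2 <- ga2
    ga1 <- vector("list", n)
    for (i in seq_len(n)) {
      sb <- sep_bwd(sc$cv2[[i]], sp$b2$dw, sp$b2$pw, gy2[[i]])
      g$stages[[l]]$b2$dw <- g$stages[[l]]$b2$dw + sb$gdw
      g$stages[[l]]$b2$pw <- g$stages[[l]]$b2$pw + sb$gpw
      g$stages[[l]]$b2$bias <- g$stages[[l]]$b2$bias + sb$gb
      ga1[[i]] <- act_bwd(sc$pre1[[i]], sc$a1[[i]], sb$gx, act)
    }
    if (cfg$batch_norm) {
      bb <- bn_bwd(sc$bn1, sp$b1$bn$gamma, ga1)
      g$stages[[l]]$b1$bn$gamma <- bb$ggamma
      g$stages[[l]]$b1$bn$beta <- bb$gbeta
      gy1 <- bb$gxs
    } else gy1 <- ga1
    gprev <- vector("list", n)
    for (i in seq_len(n)) {
      if (cfg$entry_standard[l]) {
        cb <- conv_std_bwd(sc$cv1[[i]], sp$b1$w, gy1[[i]])
        g$stages[[l]]$b1$w <- g$stages[[l]]$b1$w + cb$gw
        g$stages[[l]]$b1$bias <- g$stages[[l]]$b1$bias + cb$gb
      } else {
        cb <- sep_bwd(sc$cv1[[i]], sp$b1$dw, sp$b1$pw, gy1[[i]])
        g$stages[[l]]$b1$dw <- g$stages[[l]]$b1$dw + cb$gdw
        g$stages[[l]]$b1$pw <- g$stages[[l]]$b1$pw + cb$gpw
        g$stages[[l]]$b1$bias <- g$stages[[l]]$b1$bias + cb$gb
      }
      gprev[[i]] <- cb$gx
    }
    gcur <- gprev
  }
  g
}

# Mean cross-entropy loss and full parameter gradient for a batch.
model_loss_grad <- function(model, xs, labels, training = TRUE,
                            drop_mask = NULL) {
  fwd <- model_forward(model, xs, training = training, keep_cache = TRUE,
                       drop_mask = drop_mask)
  tgt <- ifelse(labels == 1, 1L, 2L)
  ptrue <- pmax(fwd$probs[cbind(seq_along(tgt), tgt)], 1e-12)
  loss <- -mean(log(ptrue))
  grads <- model_backward(model, fwd, labels)
  list(loss = loss, grads = grads, probs = fwd$probs, state = fwd$state)
}

#' Backbone forward pass
#'
#' Runs the five-stage backbone on one input and returns the three
#' multiscale feature maps feeding the attention branches (fine, medium,
#' coarse). Inference mode: batch-norm uses running statistics, dropout
#' is inactive, so repeated calls are identical.
#'
#' @param x `input_size x input_size x 3` array.
#' @param config The model's [dscnn_config()].
#' @param params The model's parameter list (from [model_init()]).
#' @param state Batch-norm state (from the model).
#' @return List `F1`, `F2`, `F3` of feature maps, plus `stages` (all five
#'   stage outputs).
#' @export
backbone_forward <- function(x, config, params, state = NULL) {
  d <- dims3(x)
  if (d[1] != config$input_size || d[2] != config$input_size ||
      d[3] != config$in_channels)
    stopf("input shape mismatch: expected %d x %d x %d", config$input_size,
          config$input_size, config$in_channels)
  model <- structure(list(config = config, params = params,
                          state = state %||% model_init(config, 0)$state),
                     class = "spiralnet_model")
  outs <- vector("list", 5)
  cur <- list(x)
  st <- model$state
  for (l in 1:5) {
    sp <- params$stages[[l]]
    y <- if (config$entry_standard[l])
      conv_std_fwd(cur[[1]], sp$b1$w, sp$b1$bias)$y
    else sep_fwd(cur[[1]], sp$b1$dw, sp$b1$pw, sp$b1$bias)$y
    if (config$batch_norm)
      y <- bn_fwd(list(y), sp$b1$bn$gamma, sp$b1$bn$beta, FALSE,
                  st$stages[[l]]$b1$mean, st$stages[[l]]$b1$var)$ys[[1]]
    y <- act_fwd(y, config$activation)
    y <- sep_fwd(y, sp$b2$dw, sp$b2$pw, sp$b2$bias)$y
    if (config$batch_norm)
      y <- bn_fwd(list(y), sp$b2$bn$gamma, sp$b2$bn$beta, FALSE,
                  st$stages[[l]]$b2$mean, st$stages[[l]]$b2$var)$ys[[1]]
    y <- act_fwd(y, config$activation)
    y <- pool_fwd(y)$y
    outs[[l]] <- y
    cur <- list(y)
  }
  list(F1 = outs[[config$branch_stages[1]]],
       F2 = outs[[config$branch_stages[2]]],
       F3 = outs[[config$branch_stages[3]]], stages = outs)
}

#' Project a branch feature map to the common attention shape
#'
#' Pointwise convolution to depth `d` followed by adaptive average
#' pooling to `pool_hw x pool_hw`.
#'
#' @param Fb `H x W x C` feature map with `H, W >= pool_hw`.
#' @param params List with `pw` (`C x d`) and `bias` (length `d`).
#' @param pool_hw Projected spatial size, default 7.
#' @return `pool_hw x pool_hw x d` array.
#' @export
project_branch <- function(Fb, params, pool_hw = 7L) {
  d <- dims3(Fb)
  if (d[1] < pool_hw || d[2] < pool_hw)
    stopf("branch input (%d x %d) smaller than projected size %d", d[1], d[2],
          pool_hw)
  zm <- sweep(matrix(Fb, d[1] * d[2], d[3]) %*% params$pw, 2, params$bias, "+")
  adapool_fwd(array(zm, c(d[1], d[2], ncol(params$pw))), pool_hw)$y
}

#' Multi-head self-attention over a token matrix
#'
#' Per-head scaled dot-product attention (scale `1/sqrt(d/heads)`), heads
#' concatenated, output-projected, with a residual connection and no
#' positional encoding (so the operator is permutation-equivariant).
#'
#' @param tokens `L x d` token matrix.
#' @param params List `Wq, bq, Wk, bk, Wv, bv, Wo, bo`.
#' @param heads Number of heads; must divide `d`.
#' @return `L x d` output token matrix.
#' @export
multi_head_attention <- function(tokens, params, heads = 4L) {
  mha_fwd(tokens, params, heads)$Y
}

#' Scale-gate weights over the three attention branches
#'
#' Each branch is summarized by the spatial mean of its attended map; a
#' small shared network scores each summary and a softmax over the three
#' scores yields the gate weights, which always sum to 1.
#'
#' @param branch_outputs List of three equally-shaped token matrices
#'   (`L x d`) or `p x p x d` arrays.
#' @param gate List `Wg`, `bg`, `wg` (shared gating parameters).
#' @param activation Gating nonlinearity.
#' @return Numeric vector `c(alpha1, alpha2, alpha3)`.
#' @export
gate_weights <- function(branch_outputs, gate, activation = "relu") {
  Ts <- lapply(branch_outputs, function(z) {
    if (length(dim(z)) == 3) matrix(z, prod(dim(z)[1:2]), dim(z)[3]) else z
  })
  if (!all(vapply(Ts, function(t) all(is.finite(t)), TRUE)))
    stopf("non-finite branch outputs")
  gate_forward(Ts, gate, activation)$alpha
}

#' Fuse gated branches, reduce channels, and pool
#'
#' Channel-wise concatenation of the alpha-scaled branch maps (depth
#' `3d`), pointwise reduction to `reduce_dim` channels with the model
#' nonlinearity, and spatial global average pooling.
#'
#' @param branch_outputs List of three `L x d` token matrices or
#'   `p x p x d` arrays.
#' @param alpha Gate weights summing to 1.
#' @param reduce List `pw` (`3d x reduce_dim`) and `bias`.
#' @param activation Nonlinearity after reduction.
#' @return Length-`reduce_dim` feature vector.
#' @export
fuse_reduce_pool <- function(branch_outputs, alpha, reduce,
                             activation = "relu") {
  Ts <- lapply(branch_outputs, function(z) {
    if (length(dim(z)) == 3) matrix(z, prod(dim(z)[1:2]), dim(z)[3]) else z
  })
  Fcat <- do.call(cbind, mapply(function(a, t) a * t, alpha, Ts,
                                SIMPLIFY = FALSE))
  R <- act_fwd(sweep(Fcat %*% reduce$pw, 2, reduce$bias, "+"), activation)
  colMeans(R)
}

#' Classify a pooled feature vector
#'
#' Dense layer plus softmax; element 1 is the PD posterior, element 2 the
#' healthy posterior.
#'
#' @param z Pooled feature vector.
#' @param head List `W` (`2 x length(z)`) and `b`.
#' @return Numeric `c(p_pd, p_healthy)`, summing to 1.
#' @export
classify <- function(z, head) {
  check_finite(z, "feature vector")
  softmax(as.numeric(head$W %*% z + head$b))
}

# Precise batch-norm recalibration: re-estimate the population
# statistics used at inference by one training-mode pass (dropout off)
# over reference inputs, replacing the momentum-smoothed running values,
# which lag behind rapidly changing weights early in training.
bn_recalibrate <- function(model, xs) {
  if (!model$config$batch_norm || length(xs) == 0) return(model$state)
  calm <- model
  calm$config$dropout <- 0
  model_forward(calm, xs, training = TRUE, bn_momentum = 0)$state
}

#' Predict PD posteriors for a list of inputs
#'
#' @param model A `spiralnet_model`.
#' @param xs List of `input_size x input_size x 3` arrays.
#' @return Matrix with columns `p_pd`, `p_healthy`.
#' @export
predict_proba <- function(model, xs) {
  out <- model_forward(model, xs, training = FALSE)$probs
  colnames(out) <- c("p_pd", "p_healthy")
  out
}

#' Save / load a model checkpoint
#'
#' The checkpoint stores the parameter arrays, batch-norm state, and the
#' configuration; a JSON sidecar echoes the configuration. Loading
#' validates the stored parameters against [count_parameters()].
#'
#' @param model A `spiralnet_model`.
#' @param path Checkpoint path (`.rds`).
#' @return `load_model` returns the model; `save_model` the path,
#'   invisibly.
#' @export
save_model <- function(model, path) {
  saveRDS(unclass(model), path)
  jsonlite::write_json(model$config[setdiff(names(model$config), NULL)],
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  model <- structure(obj, class = "spiralnet_model")
  model$config <- structure(model$config, class = "dscnn_config")
  stored <- length(flatten_params(model$params))
  expect <- as.integer(count_parameters(model$config))
  if (stored != expect)
    stopf("checkpoint parameter count %d does not match config (%d)", stored,
          expect)
  model
}
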