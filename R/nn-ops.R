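# Low-level differentiable operations. Feature maps are (H, W, C) arrays;
# batches are lists of such arrays. Every *_fwd returns what its *_bwd
# needs as a cache; backward passes return gradients w.r.t. inputs and
# parameters for the mean-loss convention used by the trainer.

dims3 <- function(x) {
  d <- dim(x)
  if (is.null(d)) stopf("expected an array")
  if (length(d) == 2) d <- c(d, 1L)
  d
}

as_map <- function(x) {
  if (length(dim(x)) == 2) dim(x) <- c(dim(x), 1L)
  x
}

#' Standard 2D convolution (stride 1, same padding)
#'
#' Direct sliding-window convolution with a full `K x K x M x N` kernel;
#' the parameter cost is `K^2 * M * N`. Serves as the dense reference
#' against which the factorized depthwise-separable form is checked.
#'
#' @param input `H x W x M` feature map.
#' @param weights `K x K x M x N` kernel tensor.
#' @param bias Optional length-`N` bias.
#' @return `H x W x N` feature map.
#' @export
conv_standard <- function(input, weights, bias = NULL) {
  input <- as_map(input)
  d <- dims3(input); wd <- dim(weights)
  if (length(wd) != 4 || wd[3] != d[3])
    stopf("weight shape mismatch: expected K x K x %d x N", d[3])
  K <- wd[1]; N <- wd[4]
  cols <- cpp_im2col(as.numeric(input), d[1], d[2], d[3], K, (K - 1L) %/% 2L)
  y <- cols %*% matrix(weights, K * K * d[3], N)
  if (!is.null(bias)) y <- sweep(y, 2, bias, "+")
  array(y, dim = c(d[1], d[2], N))
}

#' Depthwise-separable convolution (stride 1, same padding)
#'
#' Per-channel `K x K` spatial filtering followed by a 1x1 pointwise
#' channel mix; the parameter cost is `K^2 * M + M * N` instead of
#' `K^2 * M * N`.
#'
#' @param input `H x W x M` feature map.
#' @param dw_weights `K x K x M` depthwise kernels.
#' @param pw_weights `M x N` pointwise mixing matrix.
#' @param bias Optional length-`N` bias.
#' @return `H x W x N` feature map.
#' @export
depthwise_separable <- function(input, dw_weights, pw_weights, bias = NULL) {
  input <- as_map(input)
  d <- dims3(input); kd <- dim(dw_weights)
  if (length(kd) != 3 || kd[3] != d[3] || nrow(pw_weights) != d[3])
    stopf("weight shape mismatch for depthwise-separable convolution")
  K <- kd[1]
  u <- cpp_dw_fwd(as.numeric(input), d[1], d[2], d[3],
                  as.numeric(dw_weights), K, (K - 1L) %/% 2L)
  y <- matrix(u, d[1] * d[2], d[3]) %*% pw_weights
  if (!is.null(bias)) y <- sweep(y, 2, bias, "+")
  array(y, dim = c(d[1], d[2], ncol(pw_weights)))
}

#' Computational cost ratio of separable vs. standard convolution
#'
#' Ratio of multiply-accumulate operations of a depthwise-separable layer
#' to a standard convolution with the same geometry: `1/N + 1/K^2`.
#'
#' @param K Kernel size (>= 1).
#' @param N Output channels (>= 1).
#' @return The ratio (dimensionless).
#' @export
ccr <- function(K, N) {
  if (K < 1 || N < 1) stopf("K and N must be >= 1")
  1 / N + 1 / K^2
}

# ---- cached forward/backward pairs -----------------------------------

conv_std_fwd <- function(x, w, bias) {
  d <- dims3(x); K <- dim(w)[1]; N <- dim(w)[4]
  cols <- cpp_im2col(as.numeric(x), d[1], d[2], d[3], K, (K - 1L) %/% 2L)
  y <- sweep(cols %*% matrix(w, length(w) %/% N, N), 2, bias, "+")
  list(y = array(y, c(d[1], d[2], N)), cols = cols, d = d)
}

conv_std_bwd <- function(cache, w, gy) {
  d <- cache$d; K <- dim(w)[1]; N <- dim(w)[4]
  gym <- matrix(gy, d[1] * d[2], N)
  gw <- crossprod(cache$cols, gym)
  gcols <- tcrossprod(gym, matrix(w, length(w) %/% N, N))
  gx <- cpp_col2im(gcols, d[1], d[2], d[3], K, (K - 1L) %/% 2L)
  list(gx = array(gx, d), gw = array(gw, dim(w)), gb = colSums(gym))
}

sep_fwd <- function(x, dw, pw, bias) {
  d <- dims3(x); K <- dim(dw)[1]
  u <- cpp_dw_fwd(as.numeric(x), d[1], d[2], d[3], as.numeric(dw), K,
                  (K - 1L) %/% 2L)
  um <- matrix(u, d[1] * d[2], d[3])
  y <- sweep(um %*% pw, 2, bias, "+")
  list(y = array(y, c(d[1], d[2], ncol(pw))), u = um, x = x, d = d)
}

sep_bwd <- function(cache, dw, pw, gy) {
  d <- cache$d; K <- dim(dw)[1]
  gym <- matrix(gy, d[1] * d[2], ncol(pw))
  gpw <- crossprod(cache$u, gym)
  gu <- tcrossprod(gym, pw)
  bk <- cpp_dw_bwd(as.numeric(cache$x), as.numeric(gu), d[1], d[2], d[3],
                   as.numeric(dw), K, (K - 1L) %/% 2L)
  list(gx = array(bk$gx, d), gdw = array(bk$gw, dim(dw)), gpw = gpw,
       gb = colSums(gym))
}

# Batch normalization across a list of (H, W, C) maps, per channel.
bn_fwd <- function(xs, gamma, beta, training, rmean, rvar,
                   momentum = 0.9, eps = 1e-5) {
  d <- dims3(xs[[1]]); C <- d[3]; npx <- d[1] * d[2]
  stack <- do.call(rbind, lapply(xs, function(x) matrix(x, npx, C)))
  if (training) {
    m <- colMeans(stack)
    v <- colMeans(sweep(stack, 2, m)^2)
    rmean <- momentum * rmean + (1 - momentum) * m
    rvar <- momentum * rvar + (1 - momentum) * v
  } else { m <- rmean; v <- rvar }
  ivar <- 1 / sqrt(v + eps)
  xhat <- sweep(sweep(stack, 2, m), 2, ivar, "*")
  y <- sweep(sweep(xhat, 2, gamma, "*"), 2, beta, "+")
  ys <- lapply(seq_along(xs), function(i)
    array(y[(i - 1) * npx + seq_len(npx), ], d))
  list(ys = ys, xhat = xhat, ivar = ivar, d = d, n = length(xs),
       rmean = rmean, rvar = rvar, training = training)
}

bn_bwd <- function(cache, gamma, gys) {
  d <- cache$d; npx <- d[1] * d[2]; C <- d[3]
  g <- do.call(rbind, lapply(gys, function(x) matrix(x, npx, C)))
  ggamma <- colSums(g * cache$xhat)
  gbeta <- colSums(g)
  if (cache$training) {
    Nt <- nrow(g)
    gxh <- sweep(g, 2, gamma, "*")
    t1 <- sweep(gxh, 2, colMeans(gxh))
    t2 <- sweep(cache$xhat, 2, colMeans(gxh * cache$xhat), "*")
    gx <- sweep(t1 - t2, 2, cache$ivar, "*")
  } else {
    gx <- sweep(sweep(g, 2, gamma, "*"), 2, cache$ivar, "*")
  }
  gxs <- lapply(seq_len(cache$n), function(i)
    array(gx[(i - 1) * npx + seq_len(npx), ], d))
  list(gxs = gxs, ggamma = ggamma, gbeta = gbeta)
}

act_fwd <- function(x, kind) {
  switch(kind, relu = pmax(x, 0), tanh = tanh(x),
         stopf("unknown activation '%s'", kind))
}

act_bwd <- function(x, y, gy, kind) {
  switch(kind, relu = gy * (x > 0), tanh = gy * (1 - y^2))
}

pool_fwd <- function(x) {
  d <- dims3(x)
  r <- cpp_maxpool_fwd(as.numeric(x), d[1], d[2], d[3])
  list(y = array(r$y, c(d[1] %/% 2L, d[2] %/% 2L, d[3])), idx = r$idx, d = d)
}

pool_bwd <- function(cache, gy) {
  array(cpp_maxpool_bwd(cache$idx, as.numeric(gy), cache$d[1], cache$d[2],
                        cache$d[3]), cache$d)
}

# Adaptive average pooling windows (0-based half-open), torch convention.
adaptive_windows <- function(n_in, n_out) {
  lapply(seq_len(n_out) - 1L, function(i) {
    s <- floor(i * n_in / n_out); e <- ceiling((i + 1) * n_in / n_out)
    (s + 1L):e
  })
}

adapool_fwd <- function(x, p) {
  d <- dims3(x)
  wr <- adaptive_windows(d[1], p); wc <- adaptive_windows(d[2], p)
  y <- array(0, c(p, p, d[3]))
  for (i in seq_len(p)) for (j in seq_len(p))
    y[i, j, ] <- apply(x[wr[[i]], wc[[j]], , drop = FALSE], 3, mean)
  list(y = y, wr = wr, wc = wc, d = d)
}

adapool_bwd <- function(cache, gy) {
  gx <- array(0, cache$d)
  p <- length(cache$wr)
  for (i in seq_len(p)) for (j in seq_len(p)) {
    cnt <- length(cache$wr[[i]]) * length(cache$wc[[j]])
    for (k in seq_len(cache$d[3]))
      gx[cache$wr[[i]], cache$wc[[j]], k] <-
        gx[cache$wr[[i]], cache$wc[[j]], k] + gy[i, j, k] / cnt
  }
  gx
}

row_softmax <- function(s) {
  e <- exp(s - apply(s, 1, max))
  e / rowSums(e)
}

mha_fwd <- function(X, p, heads) {
  L <- nrow(X); d <- ncol(X)
  if (d %% heads != 0) stopf("number of heads must divide the embed dim")
  dh <- d %/% heads
  Q <- sweep(X %*% p$Wq, 2, p$bq, "+")
  K <- sweep(X %*% p$Wk, 2, p$bk, "+")
  V <- sweep(X %*% p$Wv, 2, p$bv, "+")
  O <- matrix(0, L, d); A <- vector("list", heads)
  for (h in seq_len(heads)) {
    ix <- (h - 1) * dh + seq_len(dh)
    S <- tcrossprod(Q[, ix, drop = FALSE], K[, ix, drop = FALSE]) / sqrt(dh)
    A[[h]] <- row_softmax(S)
    O[, ix] <- A[[h]] %*% V[, ix, drop = FALSE]
  }
  out <- sweep(O %*% p$Wo, 2, p$bo, "+")
  Y <- X + out
  list(Y = Y, X = X, Q = Q, K = K, V = V, O = O, A = A, dh = dh,
       heads = heads)
}

mha_bwd <- function(cache, p, gY) {
  X <- cache$X; dh <- cache$dh; heads <- cache$heads
  gO <- tcrossprod(gY, p$Wo)                    # through output projection
  gWo <- crossprod(cache$O, gY)
  gbo <- colSums(gY)
  gQ <- gK <- gV <- matrix(0, nrow(X), ncol(X))
  for (h in seq_len(heads)) {
    ix <- (h - 1) * dh + seq_len(dh)
    A <- cache$A[[h]]
    gOh <- gO[, ix, drop = FALSE]
    gA <- tcrossprod(gOh, cache$V[, ix, drop = FALSE])
    gV[, ix] <- crossprod(A, gOh)
    gS <- A * (gA - rowSums(gA * A))            # softmax backward, row-wise
    gS <- gS / sqrt(dh)
    gQ[, ix] <- gS %*% cache$K[, ix, drop = FALSE]
    gK[, ix] <- crossprod(gS, cache$Q[, ix, drop = FALSE])
  }
  gX <- gY + tcrossprod(gQ, p$Wq) + tcrossprod(gK, p$Wk) +
    tcrossprod(gV, p$Wv)
  list(gX = gX,
       gWq = crossprod(X, gQ), gbq = colSums(gQ),
       gWk = crossprod(X, gK), gbk = colSums(gK),
       gWv = crossprod(X, gV), gbv = colSums(gV),
       gWo = gWo, gbo = gbo)
}
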