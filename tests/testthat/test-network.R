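test_that("conv_standard matches direct sliding-window enumeration", {
  set.seed(1)
  x <- array(runif(5 * 5 * 2), c(5, 5, 2))
  # 1x1 identity channel matrix reproduces the input
  w_id <- array(0, c(1, 1, 2, 2)); w_id[1, 1, 1, 1] <- 1; w_id[1, 1, 2, 2] <- 1
  expect_equal(conv_standard(x, w_id), x)
  # centred delta kernel reproduces a single-channel input (same padding)
  x1 <- array(runif(25), c(5, 5, 1))
  w_delta <- array(0, c(3, 3, 1, 1)); w_delta[2, 2, 1, 1] <- 1
  expect_equal(conv_standard(x1, w_delta), x1)
  # random kernel vs pure-R oracle
  w <- array(rnorm(3 * 3 * 2 * 3), c(3, 3, 2, 3))
  expect_equal(conv_standard(x, w), conv_oracle(x, w), tolerance = 1e-12)
  expect_equal(length(w), 3^2 * 2 * 3)   # K^2*M*N = 54
  expect_equal(length(array(0, c(3, 3, 2, 4))), 72)
  expect_error(conv_standard(x, array(0, c(3, 3, 5, 2))), "mismatch")
})

test_that("depthwise-separable equals standard convolution for factorizable kernels", {
  set.seed(2)
  x <- array(runif(5 * 5 * 2), c(5, 5, 2))
  # per-channel delta + identity mix is the identity
  dw_delta <- array(0, c(3, 3, 2)); dw_delta[2, 2, ] <- 1
  expect_equal(depthwise_separable(x, dw_delta, diag(2)), x)
  # K[u,v,m,n] = dw[u,v,m] * pw[m,n] reduces to conv_standard
  dw <- array(rnorm(3 * 3 * 2), c(3, 3, 2))
  pw <- matrix(rnorm(2 * 4), 2, 4)
  w <- array(0, c(3, 3, 2, 4))
  for (m in 1:2) for (n in 1:4) w[, , m, n] <- dw[, , m] * pw[m, n]
  expect_lt(max(abs(depthwise_separable(x, dw, pw) - conv_standard(x, w))),
            1e-6)
  expect_equal(length(dw) + length(pw), 26)   # K^2*M + M*N
  expect_error(depthwise_separable(x, array(0, c(3, 3, 5)), pw), "mismatch")
})

test_that("the computational cost ratio equals enumerated operation counts", {
  expect_equal(ccr(1, 1), 2)
  expect_equal(ccr(3, 64), 0.1267361, tolerance = 1e-6)
  # enumerate multiply-accumulates on an H x W x M -> N layer
  H <- 4; W <- 4; M <- 5; N <- 64; K <- 3
  sep_ops <- H * W * K^2 * M + H * W * M * N
  std_ops <- H * W * K^2 * M * N
  expect_equal(sep_ops / std_ops, ccr(K, N))
  expect_true(all(diff(vapply(c(2, 4, 8, 16, 64), function(n) ccr(3, n),
                              0)) < 0))
  expect_error(ccr(0, 3), ">= 1")
})

test_that("backbone stage shapes follow the configuration", {
  cfg <- dscnn_config(input_size = 64, filters = c(4, 6, 8, 10, 12), d = 8,
                      heads = 2, pool_hw = 1, reduce_dim = 3,
                      gate_hidden = 3)
  m <- model_init(cfg, 3)
  x <- random_input(64)
  out <- backbone_forward(x, cfg, m$params, m$state)
  sizes <- t(vapply(out$stages, dim, integer(3)))
  expect_equal(sizes[, 1], c(32, 16, 8, 4, 2))     # halved per stage
  expect_equal(sizes[, 3], c(4, 6, 8, 10, 12))     # configured filters
  # deterministic at inference
  out2 <- backbone_forward(x, cfg, m$params, m$state)
  expect_identical(out$F3, out2$F3)
  expect_error(backbone_forward(random_input(32), cfg, m$params, m$state),
               "shape mismatch")
  # default architecture constants
  dflt <- dscnn_config()
  expect_equal(dflt$filters, c(64, 128, 256, 512, 512))
  expect_equal(dflt$d, 192)
  expect_equal(dflt$pool_hw^2, 49)
  expect_equal(dflt$reduce_dim, 32)
})

test_that("branch projection pools adaptively to the declared shape", {
  set.seed(5)
  Fb <- array(runif(8 * 8 * 3), c(8, 8, 3))
  pr <- list(pw = matrix(rnorm(3 * 6), 3, 6), bias = rnorm(6))
  z <- project_branch(Fb, pr, pool_hw = 7)
  expect_equal(dim(z), c(7, 7, 6))
  # hand-computed adaptive window: output cell (1,1) averages input rows
  # 1..2 x cols 1..2 of the pointwise-projected map
  zm <- sweep(matrix(Fb, 64, 3) %*% pr$pw, 2, pr$bias, "+")
  zf <- array(zm, c(8, 8, 6))
  expect_equal(z[1, 1, ], apply(zf[1:2, 1:2, , drop = FALSE], 3, mean))
  # interior cell (4,4): floor(3*8/7)+1 .. ceiling(4*8/7) = rows 4..5
  expect_equal(z[4, 4, ], apply(zf[4:5, 4:5, , drop = FALSE], 3, mean))
  expect_error(project_branch(array(0, c(6, 6, 3)), pr, 7), "smaller")
})

test_that("multi-head attention matches the brute-force formula and is equivariant", {
  d <- 4; L <- 3
  set.seed(6)
  X <- matrix(rnorm(L * d), L, d)
  # zero query/key weights: uniform attention; with identity value/output
  # projections each pre-residual token is the mean token
  p0 <- list(Wq = matrix(0, d, d), bq = rep(0, d),
             Wk = matrix(0, d, d), bk = rep(0, d),
             Wv = diag(d), bv = rep(0, d), Wo = diag(d), bo = rep(0, d))
  Y0 <- multi_head_attention(X, p0, heads = 1)
  pre <- Y0 - X
  for (i in 1:L) expect_equal(pre[i, ], colMeans(X), tolerance = 1e-12)
  # H = 1 brute force with explicit loops
  p <- random_attention_params(d, seed = 7)
  Y <- multi_head_attention(X, p, heads = 1)
  Q <- X %*% p$Wq + matrix(p$bq, L, d, byrow = TRUE)
  K <- X %*% p$Wk + matrix(p$bk, L, d, byrow = TRUE)
  V <- X %*% p$Wv + matrix(p$bv, L, d, byrow = TRUE)
  O <- matrix(0, L, d)
  for (i in 1:L) {
    s <- numeric(L)
    for (j in 1:L) s[j] <- sum(Q[i, ] * K[j, ]) / sqrt(d)
    a <- exp(s - max(s)); a <- a / sum(a)
    for (j in 1:L) O[i, ] <- O[i, ] + a[j] * V[j, ]
  }
  expect_equal(Y, X + O %*% p$Wo + matrix(p$bo, L, d, byrow = TRUE),
               tolerance = 1e-10)
  # permutation equivariance (no positional encoding)
  perm <- c(3, 1, 2)
  Yp <- multi_head_attention(X[perm, ], p, heads = 2)
  expect_equal(Yp, multi_head_attention(X, p, heads = 2)[perm, ],
               tolerance = 1e-12)
  expect_error(multi_head_attention(X, p, heads = 3), "divide")
})

test_that("gate weights are a softmax over shared-network scores", {
  d <- 2
  T1 <- matrix(c(1, 1, 0, 0), 2, 2)   # column means (1, 0)
  T0 <- matrix(0, 2, 2)
  gate <- list(Wg = diag(2), bg = c(0, 0), wg = c(1, 0))
  a <- gate_weights(list(T1, T0, T0), gate)
  expect_equal(a, c(exp(1), 1, 1) / (exp(1) + 2), tolerance = 1e-12)
  # identical branches share the gate equally
  expect_equal(gate_weights(list(T1, T1, T1), gate), rep(1 / 3, 3))
  set.seed(8)
  for (rep in 1:20) {
    Ts <- lapply(1:3, function(i) matrix(rnorm(8), 4, 2))
    g <- list(Wg = matrix(rnorm(6), 3, 2), bg = rnorm(3), wg = rnorm(3))
    expect_equal(sum(gate_weights(Ts, g)), 1, tolerance = 1e-12)
  }
  expect_error(gate_weights(list(T1 * NA, T0, T0), gate), "non-finite")
})

test_that("fusion concatenates alpha-scaled branches and pools to the head input", {
  d <- 4; L <- 9
  set.seed(9)
  Ts <- lapply(1:3, function(i) matrix(rnorm(L * d), L, d))
  reduce <- list(pw = diag(3 * d), bias = rep(0, 3 * d))  # identity reduce
  z <- fuse_reduce_pool(Ts, c(1, 0, 0), reduce, activation = "tanh")
  expect_length(z, 3 * d)                      # concatenated depth 3d
  expect_equal(z[(d + 1):(3 * d)], rep(0, 2 * d))  # zeroed blocks 2 and 3
  red32 <- list(pw = matrix(rnorm(3 * d * 32), 3 * d, 32), bias = rnorm(32))
  expect_length(fuse_reduce_pool(Ts, rep(1 / 3, 3), red32), 32)
})

test_that("the softmax head produces normalized PD posteriors", {
  head0 <- list(W = matrix(0, 2, 4), b = c(0, 0))
  expect_equal(classify(rep(1, 4), head0), c(0.5, 0.5))
  head2 <- list(W = rbind(c(2, 0), c(0, 0)), b = c(0, 0))
  p <- classify(c(1, 1), head2)   # logits (2, 0)
  expect_equal(p, c(exp(2), 1) / (exp(2) + 1), tolerance = 1e-12)
  set.seed(10)
  for (rep in 1:20) {
    h <- list(W = matrix(rnorm(8), 2, 4), b = rnorm(2))
    expect_equal(sum(classify(rnorm(4), h)), 1, tolerance = 1e-12)
  }
})

test_that("analytic parameter counts equal enumerated trainable entries", {
  for (cfg in list(tiny_config(),
                   dscnn_config(input_size = 64,
                                filters = c(8, 16, 32, 64, 64), d = 24,
                                heads = 2, pool_hw = 2, reduce_dim = 32,
                                gate_hidden = 16))) {
    m <- model_init(cfg, 1)
    expect_equal(as.integer(count_parameters(cfg)),
                 length(spiralnet:::flatten_params(m$params)))
  }
  # head-only contribution: C*D' + C
  bd <- attr(count_parameters(dscnn_config()), "breakdown")
  expect_equal(unname(bd["head"]), 2 * 32 + 2)
  # a separable stage is cheaper than its dense equivalent
  cfg <- tiny_config()
  sep <- unname(attr(count_parameters(cfg), "breakdown")["backbone"])
  dense <- 0; M <- 3
  for (l in 1:5) {
    Fl <- cfg$filters[l]
    dense <- dense + (9 * M * Fl + Fl) + (9 * Fl * Fl + Fl) + 2 * 2 * Fl
    M <- Fl
  }
  expect_lt(sep, dense)
})

test_that("backpropagated gradients match central finite differences", {
  cfg <- tiny_config(activation = "tanh")
  m <- model_init(cfg, 7)
  set.seed(42)
  xs <- lapply(1:2, function(i) array(runif(32 * 32 * 3), c(32, 32, 3)))
  y <- c(1, 0)
  lg <- spiralnet:::model_loss_grad(m, xs, y, training = TRUE)
  th <- spiralnet:::flatten_params(m$params)
  ana <- spiralnet:::flatten_params(lg$grads)
  set.seed(9)
  idx <- sample(length(th), ceiling(0.02 * length(th)))
  eps <- 1e-5
  loss_at <- function(v) {
    mm <- m; mm$params <- spiralnet:::unflatten_params(v, m$params)
    spiralnet:::model_loss_grad(mm, xs, y, training = TRUE)$loss
  }
  for (i in idx) {
    tp <- th; tp[i] <- tp[i] + eps
    tm <- th; tm[i] <- tm[i] - eps
    num <- (loss_at(tp) - loss_at(tm)) / (2 * eps)
    expect_lt(abs(num - ana[i]) / max(abs(num), abs(ana[i]), 1e-6), 1e-4)
  }
})

test_that("the full forward pass yields a 2-class posterior with declared shapes", {
  cfg <- dscnn_config(input_size = 64, filters = c(4, 4, 6, 6, 8), d = 12,
                      heads = 3, pool_hw = 2, reduce_dim = 5, gate_hidden = 4)
  m <- model_init(cfg, 2)
  xs <- list(random_input(64, 1), random_input(64, 2))
  fwd <- spiralnet:::model_forward(m, xs, training = FALSE,
                                   keep_cache = TRUE)
  expect_equal(dim(fwd$probs), c(2, 2))
  expect_equal(rowSums(fwd$probs), c(1, 1), tolerance = 1e-12)
  expect_equal(rowSums(fwd$alphas), c(1, 1), tolerance = 1e-12)
  tok <- fwd$cache$attn[[1]][[1]]$Y
  expect_equal(dim(tok), c(cfg$pool_hw^2, cfg$d))
  expect_equal(ncol(fwd$cache$fuse[[1]]$Fcat), 3 * cfg$d)
  expect_length(fwd$cache$fuse[[1]]$z, cfg$reduce_dim)
})

test_that("checkpoints round-trip and validate the parameter count", {
  cfg <- tiny_config()
  m <- model_init(cfg, 4)
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(m, path)
  expect_true(file.exists(paste0(path, ".json")))
  m2 <- load_model(path)
  x <- list(random_input(32))
  expect_identical(predict_proba(m, x), predict_proba(m2, x))
  # tampered checkpoint is rejected
  bad <- unclass(m); bad$params$head$b <- c(bad$params$head$b, 0)
  path2 <- withr::local_tempfile(fileext = ".rds")
  saveRDS(bad, path2)
  expect_error(load_model(path2), "parameter count")
})
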