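# Shared fixtures: tiny model configurations and toy inputs, all built
# in code at test time.

tiny_config <- function(activation = "tanh", dropout = 0) {
  dscnn_config(input_size = 32, filters = c(2, 3, 3, 4, 4), d = 8,
               heads = 2, pool_hw = 1, reduce_dim = 3, gate_hidden = 3,
               dropout = dropout, activation = activation)
}

random_input <- function(size = 32, seed = 1) {
  set.seed(seed)
  array(runif(size * size * 3), c(size, size, 3))
}

random_attention_params <- function(d, seed = 1, scale = 0.3) {
  set.seed(seed)
  rmat <- function() matrix(rnorm(d * d, sd = scale), d, d)
  list(Wq = rmat(), bq = rnorm(d, sd = scale),
       Wk = rmat(), bk = rnorm(d, sd = scale),
       Wv = rmat(), bv = rnorm(d, sd = scale),
       Wo = rmat(), bo = rnorm(d, sd = scale))
}

# Pure-R sliding-window convolution used as the independent oracle.
conv_oracle <- function(x, w) {
  H <- dim(x)[1]; W <- dim(x)[2]; M <- dim(x)[3]
  K <- dim(w)[1]; N <- dim(w)[4]; pad <- (K - 1) %/% 2
  y <- array(0, c(H, W, N))
  for (n in seq_len(N)) for (i in seq_len(H)) for (j in seq_len(W)) {
    acc <- 0
    for (u in seq_len(K)) for (v in seq_len(K)) {
      si <- i + u - 1 - pad; sj <- j + v - 1 - pad
      if (si >= 1 && si <= H && sj >= 1 && sj <= W)
        acc <- acc + sum(w[u, v, , n] * x[si, sj, ])
    }
    y[i, j, n] <- acc
  }
  y
}

# Pairwise-concordance AUC oracle (ties count one half).
auc_oracle <- function(p, label) {
  pos <- p[label == 1]; neg <- p[label == 0]
  s <- 0
  for (a in pos) for (b in neg)
    s <- s + (a > b) + 0.5 * (a == b)
  s / (length(pos) * length(neg))
}

# Brute-force Otsu: scan all 256 bin thresholds, maximize between-class
# variance.
otsu_oracle <- function(img) {
  best <- -Inf; best_t <- 0
  for (t in (1:255) / 256) {
    lo <- img[img <= t]; hi <- img[img > t]
    if (length(lo) == 0 || length(hi) == 0) next
    w0 <- length(lo) / length(img); w1 <- 1 - w0
    v <- w0 * w1 * (mean(hi) - mean(lo))^2
    if (v > best) { best <- v; best_t <- t }
  }
  best_t
}

toy_labelled_scores <- function() {
  data.frame(p_pd = c(0.95, 0.8, 0.7, 0.6, 0.45, 0.4, 0.2, 0.1),
             label = c(1, 1, 0, 1, 1, 0, 0, 0))
}
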