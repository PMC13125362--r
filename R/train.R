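#' Subject-independent split plan
#'
#' Reserves a stratified held-out test set of `round(test_fraction * n)`
#' subjects, allocated per class by largest remainder, and partitions the
#' remaining subjects into `k` stratified cross-validation folds. A
#' subject is either in the test set or in exactly one validation fold of
#' the pool, so no drawing of one subject can appear in two roles.
#'
#' @param manifest Cohort manifest (columns `subject_id`, `label`) or any
#'   data frame with one or more rows per subject.
#' @param test_fraction Fraction of subjects reserved for the test set.
#' @param k Number of cross-validation folds in the pool.
#' @param seed Integer seed.
#' @return Data frame (`subject_id`, `label`, `role`, `fold`) with
#'   `role` in `{"test", "pool"}` and `fold` in `1..k` (NA for test),
#'   class `split_plan`.
#' @export
split_subjects <- function(manifest, test_fraction = 0.2, k = 5L, seed = 1L) {
  subj <- unique(manifest[, c("subject_id", "label")])
  if (anyDuplicated(subj$subject_id))
    stopf("labels are not constant within subject")
  n <- nrow(subj)
  n_test <- round(test_fraction * n)
  classes <- sort(unique(subj$label))
  quota <- n_test * table(factor(subj$label, classes)) / n
  base <- floor(quota)
  rem <- n_test - sum(base)
  if (rem > 0) {
    extra <- order(quota - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  with_seed(seed, {
    rows <- lapply(seq_along(classes), function(ci) {
      ids <- subj$subject_id[subj$label == classes[ci]]
      ids <- sample(ids)
      nt <- base[ci]
      pool <- ids[setdiff(seq_along(ids), seq_len(nt))]
      if (length(pool) < k)
        stopf("too few subjects: class %s pool has %d < k = %d subjects",
              classes[ci], length(pool), k)
      data.frame(subject_id = c(ids[seq_len(nt)], pool),
                 label = classes[ci],
                 role = c(rep("test", nt), rep("pool", length(pool))),
                 fold = c(rep(NA_integer_, nt),
                          rep_len(seq_len(k), length(pool))),
                 stringsAsFactors = FALSE)
    })
    plan <- do.call(rbind, rows)
    plan <- plan[order(plan$subject_id), ]
    rownames(plan) <- NULL
    attr(plan, "k") <- k
    attr(plan, "seed") <- seed
    class(plan) <- c("split_plan", "data.frame")
    plan
  })
}

#' Train/validation/test subject sets for one fold
#'
#' @param plan A [split_subjects()] plan.
#' @param fold Validation fold index in `1..k`.
#' @return List of subject-id vectors `train`, `val`, `test` (pairwise
#'   disjoint).
#' @export
split_subject_sets <- function(plan, fold = 1L) {
  pool <- plan[plan$role == "pool", ]
  list(train = pool$subject_id[pool$fold != fold],
       val = pool$subject_id[pool$fold == fold],
       test = plan$subject_id[plan$role == "test"])
}

#' Training-stream augmentation policy
#'
#' The protocol bounds are fixed: rotations within +/-5 degrees,
#' isotropic scaling within \[0.9, 1.1\], shifts up to 5% of the image
#' size, and mild elastic distortion; the constructor rejects wider
#' ranges so augmented drawings stay legible.
#'
#' @param rotation Max |rotation| in degrees (<= 5).
#' @param scale Scale range within \[0.9, 1.1\].
#' @param shift Max |shift| as a fraction of image size (<= 0.05).
#' @param elastic_alpha Max elastic displacement in pixels.
#' @param elastic_sigma Gaussian smoothing SD of the displacement field.
#' @param enabled If `FALSE`, [augment()] is the identity.
#' @return An `augment_config` list.
#' @export
augment_config <- function(rotation = 5, scale = c(0.9, 1.1), shift = 0.05,
                           elastic_alpha = 4, elastic_sigma = 8,
                           enabled = TRUE) {
  if (rotation < 0 || rotation > 5) stopf("rotation must be within [0, 5] degrees")
  if (scale[1] < 0.9 || scale[2] > 1.1 || scale[1] > scale[2])
    stopf("scale range must lie within [0.9, 1.1]")
  if (shift < 0 || shift > 0.05) stopf("shift must be within [0, 0.05]")
  structure(list(rotation = rotation, scale = scale, shift = shift,
                 elastic_alpha = elastic_alpha, elastic_sigma = elastic_sigma,
                 enabled = isTRUE(enabled)), class = "augment_config")
}

smooth_field <- function(h, w, sigma, alpha) {
  g <- matrix(stats::runif(h * w, -1, 1), h, w)
  sigma <- min(sigma, floor((min(h, w) - 1) / 2) / 3)  # keep brush in-bounds
  g <- EBImage::gblur(g, sigma = sigma)
  m <- max(abs(g))
  if (m > 0) alpha * g / m else g
}

#' Randomly augment one fused input
#'
#' Draws one rotation/scale/shift/elastic sample (composed in that
#' order) and warps all channels with bilinear interpolation; the output
#' shape is preserved and a disabled config is the identity.
#'
#' @param image `H x W x C` array.
#' @param config An [augment_config()].
#' @param seed Integer seed.
#' @return Augmented array of identical shape, with the sampled
#'   parameters in attribute `draw`.
#' @export
augment <- function(image, config = augment_config(), seed = 0L) {
  if (!config$enabled) return(image)
  d <- dims3(image)
  with_seed(seed, {
    ang <- stats::runif(1, -config$rotation, config$rotation) * pi / 180
    s <- stats::runif(1, config$scale[1], config$scale[2])
    tr <- stats::runif(2, -config$shift, config$shift) * d[1:2]
    ctr <- (d[1:2] + 1) / 2
    g <- expand.grid(r = seq_len(d[1]), c = seq_len(d[2]))
    dr <- g$r - ctr[1] - tr[1]; dc <- g$c - ctr[2] - tr[2]
    cs <- cos(ang); sn <- sin(ang)
    rin <- (cs * dr - sn * dc) / s + ctr[1]
    cin <- (sn * dr + cs * dc) / s + ctr[2]
    if (config$elastic_alpha > 0) {
      rin <- rin + as.numeric(smooth_field(d[1], d[2], config$elastic_sigma,
                                           config$elastic_alpha))
      cin <- cin + as.numeric(smooth_field(d[1], d[2], config$elastic_sigma,
                                           config$elastic_alpha))
    }
    out <- cpp_bilinear(as.numeric(image), d[1], d[2], d[3], rin - 1, cin - 1)
    out <- array(out, d)
    attr(out, "draw") <- list(angle_deg = ang * 180 / pi, scale = s,
                              shift = tr)
    out
  })
}

#' Binary cross-entropy of class posteriors
#'
#' Mean of `-log p_true` over the batch; probabilities are clamped at
#' 1e-12 before the log.
#'
#' @param posteriors `n x 2` matrix (column 1 = PD posterior), rows
#'   summing to 1.
#' @param labels Length-`n` vector of 0/1 labels (1 = PD).
#' @return Non-negative scalar loss.
#' @export
bce_loss <- function(posteriors, labels) {
  tgt <- ifelse(labels == 1, 1L, 2L)
  p <- pmax(posteriors[cbind(seq_along(tgt), tgt)], 1e-12)
  -mean(log(p))
}

#' Cosine-annealing learning rate
#'
#' `eta(t) = eta_min + (eta0 - eta_min) * (1 + cos(pi * t / T)) / 2`.
#'
#' @param t Epoch in `0..T`.
#' @param T Total epochs.
#' @param eta0 Initial rate (default 1e-3).
#' @param eta_min Floor rate (default 1e-6).
#' @return Learning rate at epoch `t`.
#' @export
cosine_lr <- function(t, T, eta0 = 1e-3, eta_min = 1e-6) {
  if (any(t < 0 | t > T)) stopf("t must be within [0, T]")
  eta_min + (eta0 - eta_min) * (1 + cos(pi * t / T)) / 2
}

#' Confusion-matrix metrics
#'
#' PD is the positive class. Ratios with zero denominators are returned
#' as `NA` and named in the `undefined` element rather than silently
#' zeroed.
#'
#' @param TP,FP,TN,FN Non-negative integer counts, total > 0.
#' @return List with the counts, `accuracy`, `sensitivity`,
#'   `specificity`, `precision`, `f1`, and `undefined`.
#' @export
confusion_metrics <- function(TP, FP, TN, FN) {
  if (any(c(TP, FP, TN, FN) < 0)) stopf("counts must be non-negative")
  n <- TP + FP + TN + FN
  if (n == 0) stopf("empty confusion matrix")
  rat <- function(num, den) if (den == 0) NA_real_ else num / den
  sens <- rat(TP, TP + FN)
  spec <- rat(TN, TN + FP)
  prec <- rat(TP, TP + FP)
  f1 <- if (is.na(sens) || is.na(prec) || sens + prec == 0) NA_real_
        else 2 * prec * sens / (prec + sens)
  out <- list(TP = TP, FP = FP, TN = TN, FN = FN,
              accuracy = (TP + TN) / n, sensitivity = sens,
              specificity = spec, precision = prec, f1 = f1)
  out$undefined <- names(out)[6:9][is.na(unlist(out[6:9]))]
  out
}

score_confusion <- function(probs, labels, threshold = 0.5) {
  pred <- as.integer(probs[, 1] > threshold)
  confusion_metrics(TP = sum(pred == 1 & labels == 1),
                    FP = sum(pred == 1 & labels == 0),
                    TN = sum(pred == 0 & labels == 0),
                    FN = sum(pred == 0 & labels == 1))
}

# Early-stopping bookkeeping on a validation-F1 stream: strictly greater
# F1 counts as improvement; stop after `patience` consecutive
# non-improvements.
select_stop_epoch <- function(f1, patience = 15L) {
  best <- -Inf; best_epoch <- 0L; since <- 0L
  for (t in seq_along(f1)) {
    if (!is.na(f1[t]) && f1[t] > best) {
      best <- f1[t]; best_epoch <- t; since <- 0L
    } else since <- since + 1L
    if (since >= patience) return(list(stop_epoch = t, best_epoch = best_epoch))
  }
  list(stop_epoch = length(f1), best_epoch = best_epoch)
}

#' Training protocol configuration
#'
#' Defaults follow the selected configuration of the training protocol:
#' initial rate 1e-3 annealed to 1e-6, batch size 32, at most 150
#' epochs, early-stopping patience 15 on validation F1, decoupled weight
#' decay 1e-4 on convolution/dense weights.
#'
#' @param eta0,eta_min Initial/minimum learning rate (`eta0 > eta_min > 0`).
#' @param batch_size Mini-batch size.
#' @param epochs Maximum epochs.
#' @param patience Early-stopping patience in epochs.
#' @param weight_decay Decoupled L2 weight decay.
#' @return A `train_config` list.
#' @export
train_config <- function(eta0 = 1e-3, eta_min = 1e-6, batch_size = 32L,
                         epochs = 150L, patience = 15L,
                         weight_decay = 1e-4) {
  if (!(eta0 > eta_min && eta_min > 0)) stopf("need eta0 > eta_min > 0")
  structure(list(eta0 = eta0, eta_min = eta_min,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), patience = as.integer(patience),
                 weight_decay = weight_decay), class = "train_config")
}

adam_init <- function(theta) list(m = numeric(length(theta)),
                                  v = numeric(length(theta)), t = 0L)

adam_step <- function(theta, grad, st, lr, wd, mask, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  st$m <- beta1 * st$m + (1 - beta1) * grad
  st$v <- beta2 * st$v + (1 - beta2) * grad^2
  mhat <- st$m / (1 - beta1^st$t)
  vhat <- st$v / (1 - beta2^st$t)
  theta <- theta - lr * mhat / (sqrt(vhat) + eps) - lr * wd * mask * theta
  list(theta = theta, st = st)
}

#' Train a model under the subject-independent protocol
#'
#' Adam with decoupled weight decay and a cosine-annealed learning rate;
#' on-the-fly augmentation of the training stream only; per-epoch
#' validation metrics with early stopping on validation F1 (patience
#' from `tc`); the best-F1 checkpoint is returned. Overlapping subjects
#' between the training and validation sets are a hard error.
#'
#' @param train,val Lists with `inputs` (list of arrays), `labels`
#'   (0/1), `subject_ids` — e.g. from [preprocess_cohort()].
#' @param config Model [dscnn_config()].
#' @param tc A [train_config()].
#' @param ac An [augment_config()]; `enabled = FALSE` disables
#'   augmentation.
#' @param seed Integer seed controlling initialization, shuffling,
#'   dropout and augmentation draws.
#' @param verbose Print per-epoch progress.
#' @return List with `model` (best checkpoint), `history` (data frame),
#'   `stopped_epoch`, `best_epoch`.
#' @export
train_model <- function(train, val, config, tc = train_config(),
                        ac = augment_config(), seed = 1L, verbose = FALSE) {
  leak <- intersect(train$subject_ids, val$subject_ids)
  if (length(leak))
    stopf("subject leakage between train and val: %s",
          paste(utils::head(leak, 3), collapse = ", "))
  model <- model_init(config, seed)
  theta <- flatten_params(model$params)
  ast <- adam_init(theta)
  mask <- decay_mask(model$params)
  seeds <- derive_seeds(seed + 1L, tc$epochs * (length(train$inputs) + 1L))
  sk <- 0L
  hist <- list()
  best <- list(f1 = -Inf, epoch = 0L, params = model$params,
               state = model$state)
  since <- 0L; stopped <- tc$epochs
  for (epoch in seq_len(tc$epochs)) {
    lr <- cosine_lr(epoch - 1, tc$epochs, tc$eta0, tc$eta_min)
    sk <- sk + 1L
    ord <- with_seed(seeds[sk], sample(seq_along(train$inputs)))
    losses <- numeric(0)
    for (start in seq(1, length(ord), by = tc$batch_size)) {
      idx <- ord[start:min(start + tc$batch_size - 1, length(ord))]
      xs <- lapply(idx, function(i) {
        sk <<- sk + 1L
        if (ac$enabled) augment(train$inputs[[i]], ac, seeds[sk])
        else train$inputs[[i]]
      })
      lg <- with_seed(seeds[sk], model_loss_grad(model, xs,
                                                 train$labels[idx]))
      model$state <- lg$state
      up <- adam_step(theta, flatten_params(lg$grads), ast, lr,
                      tc$weight_decay, mask)
      theta <- up$theta; ast <- up$st
      model$params <- unflatten_params(theta, model$params)
      losses <- c(losses, lg$loss)
    }
    model$state <- bn_recalibrate(
      model, train$inputs[seq_len(min(length(train$inputs), 64L))])
    vp <- model_forward(model, val$inputs, training = FALSE)$probs
    vm <- score_confusion(vp, val$labels)
    vf1 <- if (is.na(vm$f1)) 0 else vm$f1
    hist[[epoch]] <- data.frame(epoch = epoch, lr = lr,
                                train_loss = mean(losses),
                                val_f1 = vf1, val_acc = vm$accuracy)
    if (verbose)
      message(sprintf("epoch %3d  lr %.2e  loss %.4f  val F1 %.3f", epoch,
                      lr, mean(losses), vf1))
    if (vf1 > best$f1) {
      best <- list(f1 = vf1, epoch = epoch, params = model$params,
                   state = model$state)
      since <- 0L
    } else since <- since + 1L
    if (since >= tc$patience) { stopped <- epoch; break }
  }
  model$params <- best$params
  model$state <- best$state
  list(model = model, history = do.call(rbind, hist),
       stopped_epoch = stopped, best_epoch = best$epoch)
}

#' Evaluate a model on a labelled set
#'
#' @param model Trained `spiralnet_model`.
#' @param data List with `inputs`, `labels`, `subject_ids`.
#' @param threshold Dichotomization threshold on the PD posterior.
#' @return List with `metrics` ([confusion_metrics()]) and `scores`
#'   (data frame `subject_id`, `p_pd`, `label`).
#' @export
evaluate_model <- function(model, data, threshold = 0.5) {
  probs <- predict_proba(model, data$inputs)
  list(metrics = score_confusion(probs, data$labels, threshold),
       scores = data.frame(subject_id = data$subject_ids,
                           p_pd = probs[, 1], label = data$labels,
                           stringsAsFactors = FALSE))
}

subset_cohort <- function(data, ids) {
  keep <- data$subject_ids %in% ids
  list(inputs = data$inputs[keep], labels = data$labels[keep],
       subject_ids = data$subject_ids[keep])
}
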