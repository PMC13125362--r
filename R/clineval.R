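# Deployment-oriented evaluation: ROC/PR operating characteristics,
# bootstrap subset stability, and three-zone triage at fixed clinical
# thresholds. A "samples" data frame has columns `p_pd` (predicted PD
# posterior), `label` (1 = PD), and optionally `subject_id`.

check_samples <- function(samples) {
  p <- samples$p_pd %||% samples$p
  if (is.null(p)) stopf("samples need a `p_pd` column")
  if (!all(is.finite(p))) stopf("non-finite scores")
  data.frame(p_pd = p, label = as.integer(samples$label))
}

#' ROC curve and AUC
#'
#' Threshold sweep over the unique scores (prediction positive when
#' `p_pd >= threshold`). The trapezoidal area equals the probability
#' that a random PD case outscores a random control, counting ties as
#' one half.
#'
#' @param samples Data frame with `p_pd` and `label` (both classes
#'   present).
#' @return List with `points` (data frame `threshold`, `fpr`, `tpr`) and
#'   `auc`.
#' @export
roc_curve <- function(samples) {
  s <- check_samples(samples)
  npos <- sum(s$label == 1); nneg <- sum(s$label == 0)
  if (npos == 0 || nneg == 0)
    stopf("undefined metric: both classes must be present")
  th <- sort(unique(s$p_pd), decreasing = TRUE)
  tpr <- vapply(th, function(t) sum(s$p_pd >= t & s$label == 1) / npos, 0)
  fpr <- vapply(th, function(t) sum(s$p_pd >= t & s$label == 0) / nneg, 0)
  fpr <- c(0, fpr); tpr <- c(0, tpr)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(points = data.frame(threshold = c(Inf, th), fpr = fpr, tpr = tpr),
       auc = auc)
}

#' Precision-recall curve and area
#'
#' Threshold sweep over the unique scores; the area uses step-wise
#' interpolation (sum of precision times recall increments over
#' descending thresholds), which does not inflate the area the way
#' linear interpolation would. The curve starts at recall 0 with the
#' precision of the highest-score group.
#'
#' @param samples Data frame with `p_pd` and `label` (>= 1 positive).
#' @return List with `points` (data frame `threshold`, `recall`,
#'   `precision`) and `auprc`.
#' @export
pr_curve <- function(samples) {
  s <- check_samples(samples)
  npos <- sum(s$label == 1)
  if (npos == 0) stopf("undefined metric: no positive samples")
  th <- sort(unique(s$p_pd), decreasing = TRUE)
  rec <- prec <- numeric(length(th))
  for (i in seq_along(th)) {
    sel <- s$p_pd >= th[i]
    rec[i] <- sum(sel & s$label == 1) / npos
    prec[i] <- sum(sel & s$label == 1) / sum(sel)
  }
  auprc <- sum(diff(c(0, rec)) * prec)
  list(points = data.frame(threshold = th, recall = rec, precision = prec),
       auprc = auprc)
}

#' Bootstrap-subset stability of evaluation metrics
#'
#' Draws `n_boot` subsets of size `round(fraction * N)` (without
#' replacement by default, matching a reduced-cohort reading of a 70%
#' bootstrap subset; classical with-replacement resampling via
#' `replace = TRUE`), recomputes the metrics on each, and summarizes
#' their distribution. Resamples missing a class are redrawn (capped and
#' logged in `n_redraws`).
#'
#' @param samples Data frame with `p_pd` and `label`.
#' @param fraction Subset fraction in (0, 1].
#' @param n_boot Number of resamples.
#' @param seed Integer seed.
#' @param metrics Function `samples -> named numeric vector`; defaults
#'   to AUC and AUPRC.
#' @param replace Draw with replacement.
#' @return List with `per_resample` (matrix), `summary` (median and
#'   2.5/97.5% quantiles per metric), `fraction`, `n_boot`, `n_redraws`,
#'   `seed`.
#' @export
bootstrap_eval <- function(samples, fraction = 0.7, n_boot = 100L,
                           seed = 1L, metrics = NULL, replace = FALSE) {
  s <- check_samples(samples)
  if (fraction <= 0 || fraction > 1) stopf("fraction must be in (0, 1]")
  if (is.null(metrics))
    metrics <- function(x) c(auc = roc_curve(x)$auc, auprc = pr_curve(x)$auprc)
  m <- round(fraction * nrow(s))
  if (m < 2) stopf("resample size too small")
  n_redraws <- 0L
  with_seed(seed, {
    rows <- vector("list", n_boot)
    for (b in seq_len(n_boot)) {
      for (try in 1:100) {
        idx <- sample.int(nrow(s), m, replace = replace)
        if (length(unique(s$label[idx])) == 2) break
        n_redraws <- n_redraws + 1L
        if (try == 100) stopf("cannot draw a resample containing both classes")
      }
      rows[[b]] <- metrics(s[idx, , drop = FALSE])
    }
    per <- do.call(rbind, rows)
    summ <- apply(per, 2, function(x)
      c(median = stats::median(x), lo = stats::quantile(x, 0.025,
                                                        names = FALSE),
        hi = stats::quantile(x, 0.975, names = FALSE)))
    list(per_resample = per, summary = summ, fraction = fraction,
         n_boot = n_boot, n_redraws = n_redraws, seed = seed)
  })
}

#' Triage thresholds
#'
#' @param t_low,t_high Rule-out and rule-in thresholds with
#'   `0 < t_low < t_high < 1`; defaults 0.30 and 0.70.
#' @return A `triage_thresholds` list.
#' @export
triage_thresholds <- function(t_low = 0.30, t_high = 0.70) {
  if (!(t_low > 0 && t_low < t_high && t_high < 1))
    stopf("need 0 < t_low < t_high < 1")
  structure(list(t_low = t_low, t_high = t_high),
            class = "triage_thresholds")
}

#' Three-zone triage of a PD posterior
#'
#' `p < t_low` is rule-out, `p > t_high` is rule-in, and the closed
#' interval `[t_low, t_high]` is the gray zone (boundary scores are
#' deliberately kept in the gray zone, the conservative choice for
#' screening). The three zones partition \[0, 1\].
#'
#' @param p PD posterior(s) in \[0, 1\].
#' @param thresholds A [triage_thresholds()].
#' @return Factor with levels `rule_out`, `gray`, `rule_in`.
#' @export
triage <- function(p, thresholds = triage_thresholds()) {
  if (any(p < 0 | p > 1)) stopf("p must be in [0, 1]")
  zone <- ifelse(p < thresholds$t_low, "rule_out",
                 ifelse(p > thresholds$t_high, "rule_in", "gray"))
  factor(zone, levels = c("rule_out", "gray", "rule_in"))
}

#' Predictive values at a threshold
#'
#' Dichotomizes at `p > threshold`; PPV = TP/(TP+FP), NPV = TN/(TN+FN).
#' Zero denominators yield `NA` and are flagged in `undefined`.
#'
#' @param samples Data frame with `p_pd` and `label`.
#' @param threshold Dichotomization threshold in \[0, 1\].
#' @return List `ppv`, `npv`, `counts` (TP, FP, TN, FN), `undefined`.
#' @export
ppv_npv <- function(samples, threshold) {
  if (threshold < 0 || threshold > 1) stopf("threshold must be in [0, 1]")
  s <- check_samples(samples)
  pred <- s$p_pd > threshold
  TP <- sum(pred & s$label == 1); FP <- sum(pred & s$label == 0)
  TN <- sum(!pred & s$label == 0); FN <- sum(!pred & s$label == 1)
  ppv <- if (TP + FP == 0) NA_real_ else TP / (TP + FP)
  npv <- if (TN + FN == 0) NA_real_ else TN / (TN + FN)
  list(ppv = ppv, npv = npv, counts = c(TP = TP, FP = FP, TN = TN, FN = FN),
       undefined = c(if (is.na(ppv)) "ppv", if (is.na(npv)) "npv"))
}
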