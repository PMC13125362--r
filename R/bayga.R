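#' PD-aware validation score
#'
#' `M = alpha * Sens + (1 - alpha) * Spec`; the default `alpha = 0.7`
#' weights sensitivity to reflect the clinical cost of missed PD cases.
#'
#' @param sens,spec Validation sensitivity and specificity in \[0, 1\].
#' @param alpha Sensitivity weight in (0, 1).
#' @return The score `M` in \[0, 1\].
#' @export
score_M <- function(sens, spec, alpha = 0.7) {
  if (any(sens < 0 | sens > 1) || any(spec < 0 | spec > 1))
    stopf("sens and spec must be in [0, 1]")
  if (alpha <= 0 || alpha >= 1) stopf("alpha must be in (0, 1)")
  alpha * sens + (1 - alpha) * spec
}

#' Cost-penalized tuning objective
#'
#' `J = -M + beta * C / C_max`, minimized by the optimizer; `C` is the
#' average training wall-clock cost per epoch of the candidate and
#' `C_max` the maximum observed cost.
#'
#' @param M PD-aware score.
#' @param C,C_max Candidate and maximum observed cost (> 0).
#' @param beta Cost-pressure weight (>= 0).
#' @return The objective value `J`.
#' @export
objective_J <- function(M, C, C_max, beta = 0.1) {
  if (any(C <= 0) || C_max <= 0) stopf("costs must be positive")
  if (beta < 0) stopf("beta must be >= 0")
  -M + beta * C / C_max
}

#' Hyperparameter search space
#'
#' Mixed discrete-continuous space over the tuned hyperparameters:
#' initial learning rate (log-uniform in \[1e-4, 5e-3\]), batch size in
#' \{16, 32, 64\}, dropout in \[0, 0.5\], weight decay (log-uniform in
#' \[1e-6, 1e-3\]), attention heads in \{2, 4, 6, 8\}, and attention
#' embedding dimension in \{96, 192\}.
#'
#' @param dims Optional list of dimension descriptors (`name`, `kind` in
#'   `{"log", "linear", "categorical"}`, `bounds` or `choices`)
#'   replacing the defaults.
#' @return A `search_space` list of dimension descriptors.
#' @export
search_space <- function(dims = NULL) {
  if (is.null(dims)) dims <- list(
    list(name = "eta0", kind = "log", bounds = c(1e-4, 5e-3)),
    list(name = "batch_size", kind = "categorical", choices = c(16, 32, 64)),
    list(name = "dropout", kind = "linear", bounds = c(0, 0.5)),
    list(name = "weight_decay", kind = "log", bounds = c(1e-6, 1e-3)),
    list(name = "heads", kind = "categorical", choices = c(2, 4, 6, 8)),
    list(name = "d", kind = "categorical", choices = c(96, 192)))
  for (dm in dims) {
    if (dm$kind %in% c("log", "linear")) {
      if (!all(is.finite(dm$bounds)) || dm$bounds[1] >= dm$bounds[2])
        stopf("invalid bounds for dimension '%s'", dm$name)
      if (dm$kind == "log" && dm$bounds[1] <= 0)
        stopf("log dimension '%s' needs positive bounds", dm$name)
    } else if (length(dm$choices) == 0)
      stopf("empty choices for dimension '%s'", dm$name)
  }
  names(dims) <- vapply(dims, `[[`, "", "name")
  structure(dims, class = "search_space")
}

# Transformed coordinate in [0, 1] per dimension (log10 scale for rates).
to_unit <- function(space, cand) {
  vapply(space, function(dm) {
    v <- cand[[dm$name]]
    switch(dm$kind,
      log = (log10(v) - log10(dm$bounds[1])) /
        (log10(dm$bounds[2]) - log10(dm$bounds[1])),
      linear = (v - dm$bounds[1]) / diff(dm$bounds),
      categorical = {
        k <- length(dm$choices)
        if (k == 1) 0 else (match(v, dm$choices) - 1) / (k - 1)
      })
  }, 0)
}

from_unit <- function(space, u) {
  cand <- list()
  for (i in seq_along(space)) {
    dm <- space[[i]]
    cand[[dm$name]] <- switch(dm$kind,
      log = 10^(log10(dm$bounds[1]) +
                  u[i] * (log10(dm$bounds[2]) - log10(dm$bounds[1]))),
      linear = dm$bounds[1] + u[i] * diff(dm$bounds),
      categorical = {
        k <- length(dm$choices)
        dm$choices[round(u[i] * (k - 1)) + 1]
      })
  }
  cand
}

#' Sample a random candidate
#'
#' Log dimensions are sampled log-uniformly, linear dimensions
#' uniformly, categorical dimensions uniformly over their choices.
#'
#' @param space A [search_space()].
#' @param seed Integer seed.
#' @return Named list of in-bounds values.
#' @export
sample_candidate <- function(space, seed = 0L) {
  with_seed(seed, {
    cand <- list()
    for (dm in space) {
      cand[[dm$name]] <- switch(dm$kind,
        log = 10^stats::runif(1, log10(dm$bounds[1]), log10(dm$bounds[2])),
        linear = stats::runif(1, dm$bounds[1], dm$bounds[2]),
        categorical = sample(dm$choices, 1))
    }
    cand
  })
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

#' One genetic-algorithm generation
#'
#' Tournament selection (size 2, lower objective wins), uniform
#' crossover, per-gene mutation (Gaussian with SD 10% of the transformed
#' range for continuous genes, uniform resampling for categorical), and
#' elitism: the best individual survives unchanged. Population size is
#' conserved and offspring stay in bounds.
#'
#' @param population List of candidates.
#' @param fitness Objective values (`J`, lower is better), aligned.
#' @param space A [search_space()].
#' @param seed Integer seed.
#' @param p_mut Per-gene mutation probability.
#' @param n_offspring Offspring count (default `length(population)`).
#' @return List of candidates of length `n_offspring`, the first being
#'   the elite.
#' @export
ga_generation <- function(population, fitness, space, seed = 0L,
                          p_mut = 0.25, n_offspring = length(population)) {
  if (length(population) == 0) stopf("empty population")
  with_seed(seed, {
    P <- length(population)
    elite <- population[[which.min(fitness)]]
    tournament <- function() {
      i <- sample.int(P, 2, replace = TRUE)
      population[[i[which.min(fitness[i])]]]
    }
    off <- vector("list", n_offspring)
    off[[1]] <- elite
    for (o in seq_len(n_offspring)[-1]) {
      u1 <- to_unit(space, tournament())
      u2 <- to_unit(space, tournament())
      pick <- stats::runif(length(u1)) < 0.5
      u <- ifelse(pick, u1, u2)
      for (i in seq_along(space)) {
        if (stats::runif(1) < p_mut) {
          if (space[[i]]$kind == "categorical") {
            k <- length(space[[i]]$choices)
            u[i] <- if (k == 1) 0 else (sample.int(k, 1) - 1) / (k - 1)
          } else u[i] <- clip01(u[i] + stats::rnorm(1, 0, 0.1))
        }
      }
      off[[o]] <- from_unit(space, u)
    }
    off
  })
}

# RBF-kernel Gaussian-process regression on [0,1]^D coordinates.
gp_fit <- function(X, y, lengthscale = 0.3, noise = 1e-4) {
  mu <- mean(y); sdv <- stats::sd(y)
  if (!is.finite(sdv) || sdv == 0) sdv <- 1
  ys <- (y - mu) / sdv
  K <- exp(-as.matrix(stats::dist(X))^2 / (2 * lengthscale^2))
  L <- chol(K + diag(noise + 1e-8, nrow(X)))
  alpha <- backsolve(L, forwardsolve(t(L), ys))
  list(X = X, L = L, alpha = alpha, mu = mu, sdv = sdv, ls = lengthscale)
}

gp_predict <- function(gp, Xnew) {
  d2 <- outer(rowSums(Xnew^2), rowSums(gp$X^2), "+") -
    2 * Xnew %*% t(gp$X)
  Ks <- exp(-pmax(d2, 0) / (2 * gp$ls^2))
  mean_s <- Ks %*% gp$alpha
  v <- forwardsolve(t(gp$L), t(Ks))
  var_s <- pmax(1 - colSums(v^2), 1e-12)
  list(mean = gp$mu + gp$sdv * as.numeric(mean_s),
       sd = gp$sdv * sqrt(var_s))
}

#' Bayesian-optimization proposal
#'
#' With fewer than three observations, a seeded random candidate;
#' otherwise the expected-improvement maximizer (with respect to the
#' best observed objective) of a Gaussian-process surrogate over the
#' transformed coordinates, searched over a seeded candidate pool.
#'
#' @param history List of records with elements `candidate` and `J`.
#' @param space A [search_space()].
#' @param seed Integer seed.
#' @param pool_size Candidate pool size.
#' @return An in-bounds candidate.
#' @export
bo_propose <- function(history, space, seed = 0L, pool_size = 256L) {
  if (length(history) < 3) return(sample_candidate(space, seed))
  X <- do.call(rbind, lapply(history, function(h) to_unit(space, h$candidate)))
  y <- vapply(history, `[[`, 0, "J")
  gp <- gp_fit(X, y)
  seeds <- derive_seeds(seed, pool_size)
  pool <- lapply(seeds, function(s) sample_candidate(space, s))
  Xp <- do.call(rbind, lapply(pool, function(c) to_unit(space, c)))
  pr <- gp_predict(gp, Xp)
  best <- min(y)
  imp <- best - pr$mean
  z <- imp / pr$sd
  ei <- imp * stats::pnorm(z) + pr$sd * stats::dnorm(z)
  pool[[which.max(ei)]]
}

#' Hybrid Bayesian/genetic hyperparameter optimization
#'
#' Alternates genetic-algorithm generations with Bayesian-optimization
#' proposals: each generation the GA contributes `pop - 1` offspring and
#' BO one proposal. Every evaluation is appended to the history with the
#' objective computed against the running maximum cost; at the end all
#' objectives are re-normalized against the final maximum cost so stored
#' values are mutually comparable. Failed evaluations are recorded with
#' score 0 and a flag, and the search continues.
#'
#' @param evaluator Function `candidate -> list(sens, spec, cost)`;
#'   deterministic or internally seeded.
#' @param space A [search_space()].
#' @param budget Total evaluation budget (>= `pop`).
#' @param beta Cost-pressure weight in [objective_J()].
#' @param alpha Sensitivity weight in [score_M()].
#' @param pop GA population size.
#' @param seed Integer seed.
#' @return List with `best` (candidate), `best_record`, and `history`
#'   (data frame of all evaluations, in order).
#' @export
optimize_hyperparameters <- function(evaluator, space, budget = 60L,
                                     beta = 0.1, alpha = 0.7, pop = 10L,
                                     seed = 1L) {
  if (budget < pop) stopf("budget must be >= the population size")
  seeds <- derive_seeds(seed, 2L * budget + 10L)
  si <- 0L
  nseed <- function() { si <<- si + 1L; seeds[si] }
  history <- list()
  cmax <- 0
  eval_one <- function(cand) {
    res <- tryCatch(evaluator(cand), error = function(e) NULL)
    failed <- is.null(res) || !all(is.finite(c(res$sens, res$spec, res$cost)))
    sens <- if (failed) 0 else res$sens
    spec <- if (failed) 0 else res$spec
    cost <- if (failed) max(cmax, 1) else res$cost
    cmax <<- max(cmax, cost)
    M <- score_M(sens, spec, alpha)
    rec <- list(candidate = cand, sens = sens, spec = spec, M = M,
                C = cost, J = objective_J(M, cost, cmax, beta),
                failed = failed)
    history[[length(history) + 1L]] <<- rec
    rec
  }
  population <- lapply(seq_len(pop), function(i) sample_candidate(space, nseed()))
  fitness <- vapply(population, function(c) eval_one(c)$J, 0)
  while (length(history) < budget) {
    room <- budget - length(history)
    n_new <- min(pop - 1L, room)       # GA offspring + one BO proposal
    n_ga <- max(n_new - 1L, 0L)
    off <- if (n_ga > 0)
      ga_generation(population, fitness, space, nseed(),
                    n_offspring = n_ga + 1L)[-1]
    else list()
    cands <- off
    if (n_new > n_ga)
      cands <- c(cands, list(bo_propose(history, space, nseed())))
    newfit <- vapply(cands, function(c) eval_one(c)$J, 0)
    elite_i <- which.min(fitness)      # elite survives without re-evaluation
    population <- c(population[elite_i], cands)
    fitness <- c(fitness[elite_i], newfit)
    if (length(population) > pop) {
      population <- population[seq_len(pop)]
      fitness <- fitness[seq_len(pop)]
    }
  }
  # final re-normalization against the final C_max
  for (i in seq_along(history))
    history[[i]]$J <- objective_J(history[[i]]$M, history[[i]]$C, cmax, beta)
  J <- vapply(history, `[[`, 0, "J")
  best_i <- which.min(J)
  hist_df <- data.frame(
    eval = seq_along(history),
    M = vapply(history, `[[`, 0, "M"),
    sens = vapply(history, `[[`, 0, "sens"),
    spec = vapply(history, `[[`, 0, "spec"),
    C = vapply(history, `[[`, 0, "C"),
    J = J,
    failed = vapply(history, `[[`, TRUE, "failed"))
  list(best = history[[best_i]]$candidate, best_record = history[[best_i]],
       history = hist_df, records = history)
}
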