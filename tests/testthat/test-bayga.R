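test_that("the PD-aware score weights sensitivity as documented", {
  expect_identical(score_M(1.0, 0.0, 0.7), 0.7)
  for (a in c(0.1, 0.5, 0.9))
    expect_equal(score_M(0.42, 0.42, a), 0.42)
  expect_equal(score_M(0.9, 0.8, 0.7), 0.87)
  expect_error(score_M(1.2, 0.5), "\\[0, 1\\]")
  expect_error(score_M(0.5, 0.5, alpha = 1), "alpha")
  # boundary behaviour just inside (0, 1)
  expect_equal(score_M(0.9, 0.1, 1 - 1e-9), 0.9, tolerance = 1e-6)
  expect_equal(score_M(0.9, 0.1, 1e-9), 0.1, tolerance = 1e-6)
})

test_that("the objective trades score against normalized cost", {
  expect_equal(objective_J(0.8, 5, 10, beta = 0), -0.8)
  expect_equal(objective_J(0.9, 10, 10, beta = 0.1), -0.8)
  expect_lt(objective_J(0.9, 5, 10, 0.1), objective_J(0.8, 5, 10, 0.1))
  expect_error(objective_J(0.5, 0, 10, 0.1), "positive")
  expect_error(objective_J(0.5, 1, 10, -1), "beta")
})

test_that("random candidates are in-bounds, seeded, and span all kinds", {
  sp <- search_space()
  for (s in 1:200) {
    c <- sample_candidate(sp, s)
    expect_true(c$eta0 >= 1e-4 && c$eta0 <= 5e-3)
    expect_true(c$batch_size %in% c(16, 32, 64))
    expect_true(c$dropout >= 0 && c$dropout <= 0.5)
    expect_true(c$weight_decay >= 1e-6 && c$weight_decay <= 1e-3)
    expect_true(c$heads %in% c(2, 4, 6, 8))
    expect_true(c$d %in% c(96, 192))
  }
  expect_identical(sample_candidate(sp, 99), sample_candidate(sp, 99))
  expect_error(search_space(list(list(name = "x", kind = "log",
                                      bounds = c(0, 1)))), "positive")
})

test_that("GA generations conserve size, keep the elite, and stay in bounds", {
  sp <- search_space()
  pop <- lapply(1:20, function(i) sample_candidate(sp, i))
  fit <- vapply(seq_along(pop), function(i) -i / 20, 0)  # last is best
  nxt <- ga_generation(pop, fit, sp, seed = 1)
  expect_length(nxt, 20)
  expect_identical(nxt[[1]], pop[[which.min(fit)]])
  cur <- nxt
  for (g in 1:10) {
    cur <- ga_generation(cur, runif(20, -1, 0), sp, seed = g)
    for (c in cur) {
      expect_true(c$eta0 >= 1e-4 && c$eta0 <= 5e-3)
      expect_true(c$dropout >= 0 && c$dropout <= 0.5)
      expect_true(c$batch_size %in% c(16, 32, 64))
    }
  }
  expect_error(ga_generation(list(), numeric(0), sp), "empty")
})

test_that("BO proposals fall back to random sampling and then improve a 1-D toy", {
  sp1 <- search_space(list(list(name = "x", kind = "linear",
                                bounds = c(0, 1))))
  expect_identical(bo_propose(list(), sp1, seed = 5),
                   sample_candidate(sp1, 5))
  hits <- 0
  for (s in 1:20) {
    hist <- list()
    best_at <- function() min(vapply(hist, `[[`, 0, "J"))
    for (it in 1:20) {
      cand <- bo_propose(hist, sp1, seed = s * 1000 + it)
      expect_true(cand$x >= 0 && cand$x <= 1)
      hist[[it]] <- list(candidate = cand, J = (cand$x - 0.3)^2)
      if (it == 5) b5 <- best_at()
    }
    if (best_at() <= b5) hits <- hits + 1
  }
  expect_gte(hits, 19)
})

toy_space <- function() search_space(list(
  list(name = "x", kind = "linear", bounds = c(0, 1)),
  list(name = "y", kind = "linear", bounds = c(0, 1))))

toy_evaluator <- function(cand) {
  list(sens = exp(-((cand$x - 0.62) / 0.35)^2),
       spec = exp(-((cand$y - 0.38) / 0.35)^2),
       cost = 1)
}

toy_true_max_M <- function() {
  g <- seq(0, 1, length.out = 201)          # brute-force grid oracle
  max(outer(g, g, function(x, y)
    0.7 * exp(-((x - 0.62) / 0.35)^2) + 0.3 * exp(-((y - 0.38) / 0.35)^2)))
}

test_that("the hybrid optimizer recovers a smooth toy optimum within budget", {
  truth <- toy_true_max_M()
  hits <- 0
  for (s in 1:5) {
    res <- optimize_hyperparameters(toy_evaluator, toy_space(), budget = 60,
                                    beta = 0.1, pop = 10, seed = s)
    expect_lte(nrow(res$history), 60)
    # best-so-far J is non-increasing over the evaluation sequence
    expect_true(all(diff(cummin(res$history$J)) <= 0))
    expect_equal(res$best_record$J, min(res$history$J))
    if (truth - res$best_record$M <= 0.02) hits <- hits + 1
  }
  expect_gte(hits, 4)
})

test_that("optimization is reproducible and beta = 0 ranks by M alone", {
  r1 <- optimize_hyperparameters(toy_evaluator, toy_space(), budget = 25,
                                 beta = 0.1, pop = 5, seed = 3)
  r2 <- optimize_hyperparameters(toy_evaluator, toy_space(), budget = 25,
                                 beta = 0.1, pop = 5, seed = 3)
  expect_identical(r1$history, r2$history)
  r0 <- optimize_hyperparameters(toy_evaluator, toy_space(), budget = 25,
                                 beta = 0, pop = 5, seed = 3)
  expect_equal(order(r0$history$J), order(-r0$history$M))
  # failed evaluations are flagged and do not abort the search
  bad <- function(cand) if (cand$x > 0.5) stop("boom") else
    list(sens = 0.5, spec = 0.5, cost = 1)
  rb <- optimize_hyperparameters(bad, toy_space(), budget = 15, pop = 5,
                                 seed = 1)
  expect_true(any(rb$history$failed))
  expect_equal(nrow(rb$history), 15)
  expect_lte(rb$best_record$J, min(rb$history$J))
})
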