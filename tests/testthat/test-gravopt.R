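test_that("the optimizer handles degenerate fitness and respects budgets", {
  cfg <- go_config(population = 10, iterations = 20,
                   bounds = cbind(rep(-1, 3), rep(1, 3)), seed = 2)
  res <- go_optimize(function(x) 42, cfg)
  expect_equal(res$best_fitness, 42)
  expect_true(all(res$history == 42))
  expect_lte(res$evaluations, 10 * 20)
  # patience cuts the budget short on a flat landscape
  cfgp <- go_config(population = 10, iterations = 50,
                    bounds = cbind(-1, 1), seed = 2, patience = 5)
  resp <- go_optimize(function(x) 42, cfgp)
  expect_false(is.na(resp$converged_at))
  expect_lt(resp$evaluations, 10 * 50)
})

test_that("runs are bit-reproducible under a seed and differ across seeds", {
  sphere <- function(x) sum(x^2)
  cfg <- function(s) go_config(population = 15, iterations = 30,
                               bounds = cbind(rep(-5, 4), rep(5, 4)), seed = s)
  a <- go_optimize(sphere, cfg(3))
  b <- go_optimize(sphere, cfg(3))
  c <- go_optimize(sphere, cfg(4))
  expect_identical(a, b)
  expect_false(identical(a$history, c$history))
})

test_that("positions stay in bounds and steps shrink late (exploitation)", {
  seen <- list()
  probe <- function(x) {
    seen[[length(seen) + 1]] <<- x
    sum(x^2)
  }
  cfg <- go_config(population = 10, iterations = 40,
                   bounds = cbind(rep(-2, 3), rep(2, 3)), seed = 5)
  res <- go_optimize(probe, cfg)
  P <- matrix(unlist(seen), ncol = 3, byrow = TRUE)
  expect_true(all(P >= -2 & P <= 2))
  # mean |step| in the last decile of iterations < 10% of the first decile
  by_iter <- array(t(P), c(3, 10, 40)) # dims: dim, particle, iteration
  step_size <- sapply(2:40, function(t) {
    mean(abs(by_iter[, , t] - by_iter[, , t - 1]))
  })
  expect_lt(mean(tail(step_size, 4)), 0.1 * mean(head(step_size, 4)))
  # best-so-far history is monotone non-increasing
  expect_true(all(diff(res$history) <= 0))
})

test_that("binary search on two features matches exhaustive enumeration", {
  tab <- make_stage2_table(n = 120, d = 2, n_informative = 1, seed = 6)
  scorer <- make_cv_scorer(tab$features, tab$labels, lambda = 0.05, seed = 6)
  brute <- list(c(1, 0), c(0, 1), c(1, 1))  # empty subset is repaired away
  brute_best <- brute[[which.min(vapply(brute, scorer, numeric(1)))]]
  sel <- go_select_features(tab$features, tab$labels, scorer,
                            go_config(population = 8, iterations = 15, seed = 6))
  expect_equal(unname(sel$mask), brute_best)
})

test_that("a cardinality-rewarding scorer drives selection to all features", {
  tab <- make_stage2_table(n = 60, d = 6, n_informative = 2, seed = 7)
  scorer <- function(mask) -sum(mask)  # lambda = 0: more features is better
  sel <- go_select_features(tab$features, tab$labels, scorer,
                            go_config(population = 10, iterations = 25, seed = 7))
  expect_equal(unname(sel$mask), rep(1, 6))
})

test_that("hyperparameter decoding rounds integers and inverts log scaling", {
  space <- list(lr = list(low = 1e-5, high = 1e-1, log = TRUE),
                batch = list(low = 8, high = 64, integer = TRUE))
  dec <- gravseg:::go_decode(space, c(-3, 31.6))
  expect_equal(dec$lr, 1e-3)
  expect_identical(dec$batch, 32L)
  # a failing train_fn is absorbed, not fatal
  calls <- 0
  r <- go_tune(function(p) {
    calls <<- calls + 1
    if (calls %% 7 == 0) stop("simulated training crash")
    (log10(p$lr) + 3)^2
  }, space["lr"], go_config(population = 8, iterations = 15, seed = 8))
  expect_true(is.finite(r$best_fitness))
  expect_gt(r$best_params$lr, 1e-4)
  expect_lt(r$best_params$lr, 1e-2)
})

test_that("the tuner recovers a planted log-space optimum", {
  ok <- 0
  for (s in 1:10) {
    r <- go_tune(function(p) (log10(p$lr) + 3)^2,
                 list(lr = list(low = 1e-5, high = 1e-1, log = TRUE)),
                 go_config(population = 15, iterations = 40, seed = s))
    if (r$best_params$lr > 5e-4 && r$best_params$lr < 2e-3) ok <- ok + 1
  }
  expect_gte(ok, 9)
})
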