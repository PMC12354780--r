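test_that("focal loss matches hand evaluation and degenerates to scaled BCE", {
  # single pixel, target 1, pred 0.9, alpha 0.25, gamma 2
  got <- focal_loss(matrix(0.9), matrix(1), focal_params(alpha = 0.25, gamma = 2))
  expect_equal(got, -0.25 * 0.1^2 * log(0.9), tolerance = 1e-12)
  # gamma 0, alpha 0.5: exactly half the binary cross-entropy
  set.seed(1)
  p <- matrix(runif(64, 0.05, 0.95), 8, 8)
  t <- matrix(rbinom(64, 1, 0.5), 8, 8)
  bce <- mean(-(t * log(p) + (1 - t) * log(1 - p)))
  expect_equal(focal_loss(p, t, focal_params(alpha = 0.5, gamma = 0)),
               0.5 * bce, tolerance = 1e-9)
  # perfect prediction: loss vanishes in the clipped limit
  expect_lt(focal_loss(t, t), 1e-5)
})

test_that("dice loss follows the soft set-overlap formula", {
  t <- matrix(c(1, 1, 0, 0, 0, 0, 0, 0, 0), 3, 3)
  p <- matrix(c(0, 1, 1, 0, 0, 0, 0, 0, 0), 3, 3)
  # |A| = |B| = 2, intersection 1 -> 1 - 2/4 (exact arithmetic, no smoothing)
  expect_equal(dice_loss(p, t, smooth = 0), 0.5, tolerance = 1e-12)
  expect_equal(dice_loss(t, t, smooth = 0), 0)
  disjoint <- matrix(c(0, 0, 1, 0, 0, 0, 0, 0, 0), 3, 3)
  expect_lte(abs(dice_loss(disjoint, t) - 1), 0.25) # smoothing-tolerant
  expect_equal(dice_loss(disjoint, t, smooth = 0), 1)
  # symmetry on binary inputs
  expect_equal(dice_loss(p, t), dice_loss(t, p))
  # both empty: smoothing gives zero loss
  z <- matrix(0, 3, 3)
  expect_equal(dice_loss(z, z), 0)
})

test_that("tversky family: hand counts, dice equivalence, focal exponent", {
  # hard masks with TP = 1, FP = 1, FN = 1 and alpha 0.7 / beta 0.3
  t <- matrix(c(1, 1, 0, 0), 2, 2)
  p <- matrix(c(1, 0, 1, 0), 2, 2)
  expect_equal(tversky_loss(p, t), 0.5, tolerance = 1e-12)
  expect_equal(focal_tversky_loss(p, t), 0.5^0.75, tolerance = 1e-12)
  # alpha = beta = 0.5 recovers soft dice (same smoothing on both sides)
  set.seed(2)
  ps <- matrix(runif(36), 6, 6); ts <- matrix(rbinom(36, 1, 0.4), 6, 6)
  expect_equal(tversky_loss(ps, ts, tversky_params(0.5, 0.5)),
               dice_loss(ps, ts, smooth = 0), tolerance = 1e-9)
  expect_equal(tversky_loss(ts, ts), 0)
})

test_that("composite loss is the 0.27/0.69/0.04 weighted mixture", {
  t <- matrix(c(1, 1, 0, 0), 2, 2)
  expect_equal(as.numeric(composite_loss(NULL, NULL, components = c(1, 1, 1))),
               1.0, tolerance = 1e-12)
  expect_equal(as.numeric(composite_loss(NULL, NULL,
                                         components = c(0.5, 0.2, 0.1))),
               0.277, tolerance = 1e-12)
  # linearity in components
  w <- loss_weights(0.5, 0.3, 0.2)
  expect_equal(as.numeric(composite_loss(NULL, NULL, w = w,
                                         components = c(1, 2, 3))),
               0.5 + 0.6 + 0.6, tolerance = 1e-12)
  expect_error(loss_weights(-0.1, 0.69, 0.04), "non-negative")
  got <- composite_loss(t, t)
  expect_length(attr(got, "components"), 3)
  expect_lt(as.numeric(got), 0.2) # near-perfect (dice smoothing residual)
})

test_that("hausdorff surrogate vanishes at identity and grows with offset", {
  m <- matrix(0, 32, 32); m[10:14, 10:14] <- 1
  expect_equal(hausdorff_surrogate(m, m), 0)
  # moving a predicted blob away from the target strictly increases it
  vals <- sapply(c(0, 3, 6, 9, 12), function(off) {
    p <- matrix(0, 32, 32); p[10:14 + off, 10:14 + off] <- 1
    hausdorff_surrogate(p, m)
  })
  expect_true(all(diff(vals) > 0))
  # both empty is zero by convention
  z <- matrix(0, 8, 8)
  expect_equal(hausdorff_surrogate(z, z), 0)
})

test_that("hausdorff surrogate rank-correlates with the exact distance", {
  set.seed(7)
  surr <- exact <- numeric(50)
  for (i in 1:50) {
    a <- random_mask(24, 24); b <- random_mask(24, 24)
    if (sum(a) == 0 || sum(b) == 0) { a[5, 5] <- 1; b[20, 20] <- 1 }
    surr[i] <- hausdorff_surrogate(a, b)
    exact[i] <- hausdorff_distance(a, b)
  }
  expect_gte(cor(surr, exact, method = "spearman"), 0.8)
})

test_that("loss gradients match finite differences and stay finite", {
  set.seed(8)
  p <- array(runif(64, 0.1, 0.9), c(8, 8))
  t <- array(rbinom(64, 1, 0.3), c(8, 8))
  for (pair in list(
    list(f = function(x) focal_loss(x, t), g = gravseg:::focal_grad(p, t)),
    list(f = function(x) dice_loss(x, t), g = gravseg:::dice_grad(p, t)),
    list(f = function(x) hausdorff_surrogate(x, t),
         g = gravseg:::hausdorff_surrogate_grad(p, t)),
    list(f = function(x) as.numeric(composite_loss(x, t)),
         g = gravseg:::composite_grad(p, t)))) {
    num <- p
    for (i in seq_along(p)) {
      pp <- p; pp[i] <- p[i] + 1e-6
      pm <- p; pm[i] <- p[i] - 1e-6
      num[i] <- (pair$f(pp) - pair$f(pm)) / 2e-6
    }
    expect_lt(max(abs(num - pair$g)), 1e-5)
    expect_true(all(is.finite(pair$g)))
  }
  # all-background target keeps gradients finite
  t0 <- array(0, c(8, 8))
  expect_true(all(is.finite(gravseg:::composite_grad(p, t0))))
  expect_gte(as.numeric(composite_loss(p, t0)), 0)
})

test_that("losses are non-negative and focal decreases toward the target", {
  set.seed(9)
  t <- matrix(rbinom(25, 1, 0.5), 5, 5)
  p0 <- matrix(0.5, 5, 5)
  steps <- sapply(seq(0, 0.9, by = 0.1), function(a) {
    focal_loss(p0 * (1 - a) + (t * 0.98 + 0.01) * a, t)
  })
  expect_true(all(diff(steps) < 0))
  expect_gte(focal_loss(p0, t), 0)
  expect_gte(dice_loss(p0, t), 0)
  expect_gte(tversky_loss(p0, t), 0)
})
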