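test_that("confusion counts equal the brute-force pixel loop", {
  set.seed(1)
  for (i in 1:5) {
    p <- matrix(rbinom(100, 1, 0.4), 10, 10)
    t <- matrix(rbinom(100, 1, 0.5), 10, 10)
    cc <- confusion(p, t)
    oc <- oracle_confusion(p, t)
    expect_equal(c(tp = cc$tp, fp = cc$fp, tn = cc$tn, fn = cc$fn), oc)
    expect_identical(cc$tp + cc$fp + cc$tn + cc$fn, 100L)
  }
  t <- matrix(rbinom(64, 1, 0.3), 8, 8)
  cc <- confusion(t, t)
  expect_identical(cc$fp + cc$fn, 0L)
  cn <- confusion(1 - t, t)
  expect_identical(cn$tp + cn$tn, 0L)
  expect_error(confusion(matrix(0.5, 2, 2), matrix(1, 2, 2)), "binary")
})

test_that("scalar metrics follow the confusion-count formulas", {
  m <- scalar_metrics(structure(list(tp = 8, fp = 2, tn = 85, fn = 5),
                                class = "confusion_counts"))
  expect_equal(m$accuracy, 0.93)
  expect_equal(m$precision, 0.8)
  expect_equal(m$recall, 8 / 13)
  expect_identical(m$recall, m$sensitivity)
  expect_equal(m$specificity, 85 / 87)
  expect_equal(m$f1, 2 * 0.8 * (8 / 13) / (0.8 + 8 / 13))
  perfect <- scalar_metrics(structure(list(tp = 10, fp = 0, tn = 90, fn = 0),
                                      class = "confusion_counts"))
  expect_equal(unname(unlist(perfect[c("accuracy", "precision", "recall",
                                       "specificity", "f1", "mcc")])),
               rep(1, 6))
  # zero denominators: reported as 0 and flagged
  degen <- scalar_metrics(structure(list(tp = 0, fp = 0, tn = 50, fn = 0),
                                    class = "confusion_counts"))
  expect_equal(degen$precision, 0)
  expect_true("precision" %in% degen$degenerate)
})

test_that("dice and iou follow set arithmetic and their algebraic identity", {
  a <- matrix(0, 4, 4); a[1, 1:2] <- 1
  b <- matrix(0, 4, 4); b[1, 2:3] <- 1
  di <- dice_iou(a, b)
  expect_equal(unname(di["dice"]), 0.5)
  expect_equal(unname(di["iou"]), 1 / 3)
  expect_equal(unname(dice_iou(a, a)), c(1, 1))
  expect_equal(unname(dice_iou(matrix(0, 2, 2), matrix(0, 2, 2))), c(1, 1))
  set.seed(2)
  for (i in 1:100) {
    p <- matrix(rbinom(64, 1, 0.4), 8, 8)
    t <- matrix(rbinom(64, 1, 0.4), 8, 8)
    di <- dice_iou(p, t)
    expect_equal(unname(di["dice"]), unname(2 * di["iou"] / (1 + di["iou"])),
                 tolerance = 1e-12)
  }
})

test_that("exact hausdorff equals the all-pairs oracle and is a metric", {
  a <- matrix(0, 8, 8); a[1, 1] <- 1
  b <- matrix(0, 8, 8); b[4, 5] <- 1
  expect_equal(as.numeric(hausdorff_distance(a, b)), 5)
  expect_equal(as.numeric(hausdorff_distance(a, a)), 0)
  set.seed(3)
  for (i in 1:20) {
    A <- random_mask(20, 20); B <- random_mask(20, 20)
    if (sum(A) == 0 || sum(B) == 0) next
    expect_identical(as.numeric(hausdorff_distance(A, B)), oracle_hausdorff(A, B))
    expect_identical(as.numeric(hausdorff_distance(A, B)),
                     as.numeric(hausdorff_distance(B, A)))
  }
  # triangle inequality on seeded triples
  for (i in 1:10) {
    A <- random_mask(16, 16); B <- random_mask(16, 16); C <- random_mask(16, 16)
    if (sum(A) * sum(B) * sum(C) == 0) next
    expect_lte(as.numeric(hausdorff_distance(A, C)),
               as.numeric(hausdorff_distance(A, B)) +
                 as.numeric(hausdorff_distance(B, C)) + 1e-12)
  }
  # empty-mask conventions
  z <- matrix(0, 8, 8)
  one_empty <- hausdorff_distance(z, a)
  expect_equal(as.numeric(one_empty), sqrt(128))
  expect_match(attr(one_empty, "degenerate"), "one mask")
  both <- hausdorff_distance(z, z)
  expect_equal(as.numeric(both), 0)
})

test_that("rank-based AUC behaves like the Mann-Whitney statistic", {
  y <- rep(c(0, 1), each = 50)
  s <- c(runif(50, 0, 0.4), runif(50, 0.6, 1))
  expect_equal(auc_score(s, y), 1)
  set.seed(4)
  yr <- rbinom(1e4, 1, 0.5)
  sr <- runif(1e4)
  a <- auc_score(sr, yr)
  expect_lt(abs(a - 0.5), 0.02)
  expect_equal(auc_score(-sr, yr), 1 - a, tolerance = 1e-12)
  expect_warning(single <- auc_score(sr[1:5], rep(1, 5)), "single-class")
  expect_true(is.na(single))
})

test_that("metrics_report assembles a coherent per-structure row", {
  set.seed(5)
  t <- random_mask(24, 24)
  p <- t
  p[2, 2] <- 1 - p[2, 2]
  rep <- metrics_report(p, t)
  expect_true(all(c("accuracy", "dice", "iou", "hausdorff", "auc", "mcc")
                  %in% names(rep)))
  expect_gt(rep$dice, 0.9)
  expect_true(rep$mcc >= -1 && rep$mcc <= 1)
})
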