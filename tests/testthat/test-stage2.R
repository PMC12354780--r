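test_that("region features match hand counts on a toy square", {
  img <- matrix(0.5, 10, 10)
  mask <- matrix(0, 10, 10)
  mask[3:5, 3:5] <- 1  # rows/cols 2-4 in 0-based coordinates
  f <- extract_features(img, mask, sample_id = "toy")
  expect_equal(nrow(f), 1)
  expect_equal(f$area, 9)
  expect_equal(c(f$centroid_row, f$centroid_col), c(3, 3))
  expect_equal(c(f$bbox_min_row, f$bbox_min_col, f$bbox_max_row, f$bbox_max_col),
               c(2, 2, 5, 5))
  expect_equal(f$perimeter, 8)  # all but the center pixel touch background
  # constant in-region intensity: degenerate texture
  expect_equal(f$sd_intensity, 0)
  expect_equal(f$glcm_energy, 1)
  expect_equal(f$glcm_contrast, 0)
})

test_that("disjoint blobs produce one row each; small ones are dropped", {
  img <- matrix(runif(400), 20, 20)
  mask <- matrix(0, 20, 20)
  mask[2:5, 2:5] <- 1
  mask[12:16, 12:16] <- 1
  mask[19, 19] <- 1  # below min area
  f <- extract_features(img, mask, min_component_area = 5)
  expect_equal(nrow(f), 2)
  expect_identical(f$area, c(16L, 25L))
  # area equals a brute-force count of labelled pixels
  lab <- gravseg:::cpp_label8(mask)
  for (i in seq_len(nrow(f))) {
    expect_equal(f$area[i], sum(lab == f$component_id[i]))
  }
})

test_that("features are translation-equivariant", {
  set.seed(1)
  img <- matrix(runif(24 * 24), 24, 24)
  mask <- matrix(0, 24, 24)
  mask[4:9, 5:8] <- 1
  mask[6, 6] <- 1
  f0 <- extract_features(img, mask)
  dr <- 7; dc <- 9
  img2 <- matrix(0, 24, 24); mask2 <- matrix(0, 24, 24)
  img2[(4:9) + dr, (5:8) + dc] <- img[4:9, 5:8]
  mask2[(4:9) + dr, (5:8) + dc] <- mask[4:9, 5:8]
  f1 <- extract_features(img2, mask2)
  expect_equal(f1$centroid_row, f0$centroid_row + dr)
  expect_equal(f1$centroid_col, f0$centroid_col + dc)
  expect_equal(f1$bbox_min_row, f0$bbox_min_row + dr)
  expect_equal(f1$bbox_max_col, f0$bbox_max_col + dc)
  invariant <- setdiff(region_feature_names(),
                       c("centroid_row", "centroid_col", "bbox_min_row",
                         "bbox_min_col", "bbox_max_row", "bbox_max_col"))
  for (col in invariant) expect_equal(f1[[col]], f0[[col]], tolerance = 1e-12)
})

test_that("empty masks yield a zero sample row flagged has_regions = FALSE", {
  img <- matrix(0.3, 12, 12)
  f <- extract_features(img, matrix(0, 12, 12), sample_id = "e")
  expect_equal(nrow(f), 0)
  row <- sample_feature_row(f, sample_id = "e")
  expect_false(row$has_regions)
  expect_equal(row$n_components, 0)
  expect_equal(row$total_area, 0)
})

test_that("the booster separates planted features and is deterministic", {
  tab <- make_stage2_table(n = 240, d = 10, n_informative = 4, effect = 2,
                           seed = 3)
  clf <- train_classifier(tab$features, tab$labels,
                          booster_config(n_rounds = 40, seed = 3))
  expect_gte(clf$cv_mean[["accuracy"]], 0.95)
  p <- predict(clf, tab$features)
  expect_true(all(abs(rowSums(p) - 1) < 1e-9))
  expect_gte(mean((p[, "p_present"] >= 0.5) == tab$labels), 0.95)
  # retraining with the same seed reproduces the predictions bit-for-bit
  clf2 <- train_classifier(tab$features, tab$labels,
                           booster_config(n_rounds = 40, seed = 3))
  expect_identical(predict(clf2, tab$features), p)
})

test_that("label-shuffled training scores at chance AUC", {
  tab <- make_stage2_table(n = 500, d = 10, n_informative = 4, seed = 4)
  set.seed(99)
  y_shuffled <- sample(tab$labels)
  clf <- train_classifier(tab$features, y_shuffled,
                          booster_config(n_rounds = 40, seed = 4))
  expect_gt(clf$cv_mean[["auc"]], 0.4)
  expect_lt(clf$cv_mean[["auc"]], 0.6)
})

test_that("prediction contracts: masks, missing columns, empty tables", {
  tab <- make_stage2_table(n = 120, d = 8, n_informative = 3, seed = 5)
  clf <- train_classifier(tab$features, tab$labels,
                          booster_config(n_rounds = 20, seed = 5),
                          feature_mask = c("f1", "f2", "f3", "f6"))
  expect_identical(clf$feature_names, c("f1", "f2", "f3", "f6"))
  expect_error(train_classifier(tab$features, tab$labels,
                                feature_mask = c("f1", "nope")), "nope")
  expect_error(train_classifier(tab$features, rep(1, 120)), "both classes")
  expect_error(predict(clf, tab$features[, 1:2]), "missing feature")
  empty <- predict(clf, tab$features[0, , drop = FALSE])
  expect_equal(nrow(empty), 0)
})
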