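test_that("min-max normalization rescales to [0,1] and is idempotent", {
  expect_equal(min_max_normalize(matrix(c(2, 6, 10), 1)),
               matrix(c(0, 0.5, 1), 1))
  expect_equal(min_max_normalize(matrix(5, 3, 3)), matrix(0, 3, 3))
  set.seed(11)
  img <- matrix(rnorm(64), 8, 8)
  out <- min_max_normalize(img)
  expect_equal(min(out), 0)
  expect_equal(max(out), 1)
  expect_equal(min_max_normalize(out), out)
})

test_that("grayscale conversion uses the 0.299/0.587/0.114 luma weights", {
  px <- function(r, g, b) array(c(r, g, b), c(1, 1, 3))
  expect_equal(as.numeric(to_grey(px(1, 1, 1))), 1.0)
  expect_equal(as.numeric(to_grey(px(1, 0, 0))), 0.299)
  expect_equal(as.numeric(to_grey(px(0, 1, 0))), 0.587)
  expect_error(to_grey(array(0, c(2, 2, 4))), "3")
})

test_that("bilateral filter matches the double-loop oracle and its limits", {
  p <- bilateral_params(sigma_s = 1.5, sigma_r = 0.1)
  const <- matrix(0.4, 9, 9)
  expect_equal(bilateral(const, p), const)

  set.seed(3)
  img <- matrix(runif(16 * 16), 16, 16)
  got <- bilateral(img, p)
  want <- oracle_bilateral(img, 1.5, 0.1, p$window_radius)
  expect_lt(max(abs(got - want)), 1e-6)

  # convex-combination bound: output within local window min/max
  r <- p$window_radius
  for (x in seq(2, 15, by = 4)) for (y in seq(2, 15, by = 4)) {
    win <- img[max(1, x - r):min(16, x + r), max(1, y - r):min(16, y + r)]
    expect_gte(got[x, y], min(win) - 1e-12)
    expect_lte(got[x, y], max(win) + 1e-12)
  }
})

test_that("gaussian blur preserves constants, mass, and the kernel peak", {
  const <- matrix(2.5, 8, 8)
  expect_equal(gaussian_blur(const, 1), const, tolerance = 1e-12)
  imp <- matrix(0, 17, 17); imp[9, 9] <- 1
  out <- gaussian_blur(imp, 1)
  k <- exp(-((-3:3)^2) / 2); k <- k / sum(k)
  expect_lt(abs(out[9, 9] - k[4]^2), 1e-6)
  expect_lt(abs(sum(out) - 1), 1e-6)
  expect_error(gaussian_blur(const, -1), "sigma")
})

test_that("z-score standardizes to zero mean and unit sd", {
  expect_equal(zscore(matrix(c(0, 2), 1)), matrix(c(-1, 1), 1))
  set.seed(4)
  img <- matrix(rnorm(100, 5, 3), 10, 10)
  z <- zscore(img)
  expect_lt(abs(mean(z)), 1e-9)
  expect_lt(abs(sqrt(mean(z^2)) - 1), 1e-9)
  expect_warning(z0 <- zscore(matrix(1, 4, 4)), "constant")
  expect_equal(z0, matrix(0, 4, 4))
})

test_that("geometric augmentations preserve label structure", {
  s <- forge_sample(tiny_spec(32, seed = 9, n_tumors = 2L))
  # 180 degrees twice is the identity, exactly
  r180 <- transform_sample(transform_sample(s, "rotate", 180), "rotate", 180)
  expect_identical(r180$label_map, s$label_map)
  expect_equal(r180$image, s$image)
  # flips permute pixels: class counts unchanged
  hf <- transform_sample(s, "hflip")
  expect_identical(table(hf$label_map), table(s$label_map))
  expect_identical(transform_sample(hf, "hflip")$label_map, s$label_map)
  # 80-degree rotation: nearest-neighbor resampling perturbs class counts
  # by less than 5% of the liver area
  r80 <- transform_sample(s, "rotate", 80)
  liver_area <- sum(s$label_map >= 1)
  for (cls in 1:2) {
    expect_lt(abs(sum(r80$label_map == cls) - sum(s$label_map == cls)),
              0.05 * liver_area)
  }
  # contrast leaves the labels untouched
  ct <- transform_sample(s, "contrast", 1.2)
  expect_identical(ct$label_map, s$label_map)
  expect_false(identical(ct$image, s$image))
})

test_that("augment draws deterministically from the plan", {
  s <- forge_sample(tiny_spec(32, seed = 10))
  plan <- augmentation_plan(apply_probability = 1)
  out <- augment(s, plan, seed = 2)
  # all four rotations + both flips + contrast at probability 1
  expect_length(out, 7)
  expect_identical(lapply(augment(s, plan, seed = 2), `[[`, "label_map"),
                   lapply(out, `[[`, "label_map"))
  expect_error(augmentation_plan(rotations = c(90, 400)), "rotation")
})

test_that("split apportionment conserves n and matches exact fractions", {
  expect_identical(split_counts(10), c(train = 7L, val = 2L, test = 1L))
  r <- split_ratios()
  set.seed(6)
  for (n in c(3:12, sample(13:1e6, 40))) {
    cnt <- split_counts(n, r)
    expect_identical(sum(cnt), as.integer(n))
  }
})

test_that("split assignment partitions the manifest deterministically", {
  man <- fake_manifest(201)
  a <- assign_splits(man, seed = 5)
  b <- assign_splits(man, seed = 5)
  expect_identical(a, b)
  expect_identical(sum(a$split == "train"), 141L)
  expect_false(any(is.na(a$split)))
  expect_identical(sort(unique(a$split)), c("test", "train", "val"))
})
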