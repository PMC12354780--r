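# Preprocessing: intensity normalization, RGB-to-grey, edge-preserving
# denoising, augmentation, and train/val/test apportionment.

#' Min-max intensity normalization
#'
#' Rescales to `(i - i_min) / (i_max - i_min)`; a constant image maps to
#' all zeros. Multi-channel inputs are normalized per channel.
#'
#' @param img numeric matrix or H x W x C array.
#' @return normalized array of the same shape, range `[0, 1]`.
#' @export
min_max_normalize <- function(img) {
  if (length(img) == 0) stop("empty image", call. = FALSE)
  if (!all(is.finite(img))) stop("image contains non-finite values", call. = FALSE)
  norm1 <- function(x) {
    lo <- min(x); hi <- max(x)
    if (hi > lo) (x - lo) / (hi - lo) else x * 0
  }
  if (length(dim(img)) == 3L) {
    out <- img
    for (ch in seq_len(dim(img)[3])) out[, , ch] <- norm1(img[, , ch])
    out
  } else {
    norm1(img)
  }
}

#' RGB to grayscale by luma weighting
#'
#' `grey = 0.299 R + 0.587 G + 0.114 B`; channels are expected to be
#' min-max normalized already.
#'
#' @param rgb H x W x 3 array.
#' @return numeric matrix.
#' @export
to_grey <- function(rgb) {
  d <- dim(rgb)
  if (length(d) != 3L || d[3] != 3L) {
    stop("to_grey() expects an H x W x 3 array, got dims: ",
         paste(d, collapse = " x "), call. = FALSE)
  }
  0.299 * rgb[, , 1] + 0.587 * rgb[, , 2] + 0.114 * rgb[, , 3]
}

#' Bilateral filter parameters
#'
#' @param sigma_s spatial kernel width, pixels (> 0).
#' @param sigma_r range (intensity) kernel width (> 0).
#' @param window_radius half-width of the square window; defaults to
#'   `ceiling(2 * sigma_s)` which captures > 95% of the spatial Gaussian
#'   mass.
#' @return list of class `bilateral_params`.
#' @export
bilateral_params <- function(sigma_s, sigma_r, window_radius = NULL) {
  stopifnot_scalar_number(sigma_s, "sigma_s", positive = TRUE)
  stopifnot_scalar_number(sigma_r, "sigma_r", positive = TRUE)
  if (is.null(window_radius)) window_radius <- ceiling(2 * sigma_s)
  if (window_radius < 1) stop("window_radius must be >= 1", call. = FALSE)
  structure(list(sigma_s = sigma_s, sigma_r = sigma_r,
                 window_radius = as.integer(window_radius)),
            class = "bilateral_params")
}

#' Edge-preserving bilateral filter
#'
#' Each output pixel is the weight-normalized sum over the window of
#' neighbor intensities, weighted by a spatial Gaussian
#' `exp(-d^2 / (2 sigma_s^2))` and a range Gaussian on intensity
#' differences `exp(-dI^2 / (2 sigma_r^2))`. Windows are truncated at the
#' image border (only in-bounds neighbors contribute), so every output
#' pixel is a convex combination of window intensities.
#'
#' @param img numeric matrix.
#' @param p a [bilateral_params()].
#' @return filtered matrix.
#' @export
bilateral <- function(img, p) {
  stopifnot(inherits(p, "bilateral_params"))
  H <- nrow(img); W <- ncol(img); r <- p$window_radius
  num <- matrix(0, H, W); den <- matrix(0, H, W)
  inv2ss <- 1 / (2 * p$sigma_s^2); inv2sr <- 1 / (2 * p$sigma_r^2)
  for (dh in -r:r) {
    rows_src <- seq_len(H) + dh
    rok <- rows_src >= 1 & rows_src <= H
    for (dw in -r:r) {
      cols_src <- seq_len(W) + dw
      cok <- cols_src >= 1 & cols_src <= W
      ws <- exp(-(dh^2 + dw^2) * inv2ss)
      s <- img[rows_src[rok], cols_src[cok], drop = FALSE]
      ctr <- img[rok, cok, drop = FALSE]
      w <- ws * exp(-(s - ctr)^2 * inv2sr)
      num[rok, cok] <- num[rok, cok] + w * s
      den[rok, cok] <- den[rok, cok] + w
    }
  }
  num / den
}

# symmetric (edge-repeating) reflection of out-of-range indices into 1..n
reflect_index <- function(i, n) {
  i <- ifelse(i < 1, 1 - i, i)
  i <- ifelse(i > n, 2 * n + 1 - i, i)
  # repeat until inside (only matters for very small images / large offsets)
  while (any(i < 1 | i > n)) {
    i <- ifelse(i < 1, 1 - i, i)
    i <- ifelse(i > n, 2 * n + 1 - i, i)
  }
  i
}

#' Separable Gaussian blur
#'
#' Convolution with a normalized Gaussian kernel (half-width
#' `ceiling(3 sigma)`), applied along rows then columns with symmetric
#' border reflection.
#'
#' @param img numeric matrix.
#' @param sigma kernel standard deviation in pixels (> 0).
#' @return blurred matrix.
#' @export
gaussian_blur <- function(img, sigma) {
  stopifnot_scalar_number(sigma, "sigma", positive = TRUE)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  blur1 <- function(m) { # along rows (first dim)
    out <- matrix(0, nrow(m), ncol(m))
    for (j in seq_along(k)) {
      idx <- reflect_index(seq_len(nrow(m)) + (j - r - 1L), nrow(m))
      out <- out + k[j] * m[idx, , drop = FALSE]
    }
    out
  }
  t(blur1(t(blur1(img))))
}

#' Z-score standardization
#'
#' Centers to mean 0 and scales to unit standard deviation. A constant
#' image returns zeros with a warning rather than dividing by zero.
#'
#' @param img numeric matrix or array.
#' @return standardized array of the same shape.
#' @export
zscore <- function(img) {
  s <- sqrt(mean((img - mean(img))^2)) # population SD: {0,2} -> {-1,+1}
  if (!is.finite(s) || s == 0) {
    warning("constant image: z-score returns zeros")
    return(img * 0)
  }
  (img - mean(img)) / s
}

#' Augmentation plan
#'
#' The canonical augmentation set: multi-angle rotations (80, 90, 180,
#' 270 degrees), horizontal/vertical flips, multiplicative contrast
#' adjustment and isotropic scaling. Geometric transforms are applied
#' identically to image and label map (nearest-neighbor for the labels);
#' contrast touches the image only.
#'
#' @param rotations rotation angles in degrees.
#' @param hflip,vflip include horizontal / vertical flips.
#' @param contrast_range multiplicative contrast factor interval.
#' @param scale_range isotropic zoom factor interval.
#' @param apply_probability per-transform inclusion probability.
#' @return list of class `augmentation_plan`.
#' @export
augmentation_plan <- function(rotations = c(80, 90, 180, 270),
                              hflip = TRUE, vflip = TRUE,
                              contrast_range = c(0.9, 1.1),
                              scale_range = NULL,
                              apply_probability = 0.5) {
  if (apply_probability < 0 || apply_probability > 1) {
    stop("apply_probability must lie in [0, 1]", call. = FALSE)
  }
  if (length(rotations) && any(rotations <= 0 | rotations >= 360)) {
    stop("rotation angles must lie in (0, 360) degrees", call. = FALSE)
  }
  structure(list(rotations = rotations, hflip = isTRUE(hflip),
                 vflip = isTRUE(vflip), contrast_range = contrast_range,
                 scale_range = scale_range,
                 apply_probability = apply_probability),
            class = "augmentation_plan")
}

# --- elementary geometric transforms -----------------------------------

rot90k <- function(m, k) { # counter-clockwise quarter turns
  k <- k %% 4
  if (k == 0) return(m)
  for (i in seq_len(k)) m <- t(m)[rev(seq_len(ncol(m))), , drop = FALSE]
  m
}

# Rotation by an arbitrary angle (degrees, counter-clockwise) about the
# image center via inverse mapping; reflect padding at the borders.
rotate_free <- function(m, angle, interp = c("bilinear", "nearest")) {
  interp <- match.arg(interp)
  H <- nrow(m); W <- ncol(m)
  th <- angle * pi / 180
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  rr <- matrix(seq_len(H), H, W) - cy
  cc <- matrix(seq_len(W), H, W, byrow = TRUE) - cx
  # inverse rotation of output coords into the source frame
  sr <- cos(th) * rr + sin(th) * cc + cy
  sc <- -sin(th) * rr + cos(th) * cc + cx
  sample_at(m, sr, sc, interp)
}

scale_free <- function(m, factor, interp = c("bilinear", "nearest")) {
  interp <- match.arg(interp)
  H <- nrow(m); W <- ncol(m)
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  sr <- (matrix(seq_len(H), H, W) - cy) / factor + cy
  sc <- (matrix(seq_len(W), H, W, byrow = TRUE) - cx) / factor + cx
  sample_at(m, sr, sc, interp)
}

sample_at <- function(m, sr, sc, interp) {
  H <- nrow(m); W <- ncol(m)
  if (interp == "nearest") {
    ri <- reflect_index(round(sr), H)
    ci <- reflect_index(round(sc), W)
    out <- m[cbind(as.vector(ri), as.vector(ci))]
  } else {
    r0 <- floor(sr); c0 <- floor(sc)
    fr <- sr - r0; fc <- sc - c0
    g <- function(ri, ci) m[cbind(as.vector(reflect_index(ri, H)),
                                  as.vector(reflect_index(ci, W)))]
    out <- (1 - fr) * (1 - fc) * g(r0, c0) + (1 - fr) * fc * g(r0, c0 + 1) +
      fr * (1 - fc) * g(r0 + 1, c0) + fr * fc * g(r0 + 1, c0 + 1)
  }
  matrix(out, H, W)
}

apply_channels <- function(img, f) {
  if (length(dim(img)) == 3L) {
    out <- img
    for (ch in seq_len(dim(img)[3])) out[, , ch] <- f(img[, , ch])
    out
  } else {
    f(img)
  }
}

#' Apply a single augmentation transform to a phantom sample
#'
#' Geometric transforms hit image and label map identically (labels via
#' nearest-neighbor or exact permutations for quarter turns / flips);
#' contrast rescales the image about its mean and leaves labels alone.
#'
#' @param sample a `phantom_sample`.
#' @param type one of `"rotate"`, `"hflip"`, `"vflip"`, `"contrast"`,
#'   `"scale"`.
#' @param value angle in degrees (rotate), contrast factor, or zoom
#'   factor; ignored for flips.
#' @return transformed `phantom_sample`.
#' @export
transform_sample <- function(sample, type, value = NULL) {
  img <- sample$image; lab <- sample$label_map
  switch(type,
    rotate = {
      if (value %% 90 == 0) {
        k <- (value %/% 90) %% 4
        img <- apply_channels(img, function(m) rot90k(m, k))
        lab <- rot90k(lab, k)
      } else {
        img <- apply_channels(img, function(m) rotate_free(m, value, "bilinear"))
        lab <- rotate_free(lab, value, "nearest")
      }
    },
    hflip = {
      img <- apply_channels(img, function(m) m[, rev(seq_len(ncol(m))), drop = FALSE])
      lab <- lab[, rev(seq_len(ncol(lab))), drop = FALSE]
    },
    vflip = {
      img <- apply_channels(img, function(m) m[rev(seq_len(nrow(m))), , drop = FALSE])
      lab <- lab[rev(seq_len(nrow(lab))), , drop = FALSE]
    },
    contrast = {
      img <- apply_channels(img, function(m) clip01((m - mean(m)) * value + mean(m)))
    },
    scale = {
      img <- apply_channels(img, function(m) scale_free(m, value, "bilinear"))
      lab <- scale_free(lab, value, "nearest")
    },
    stop("unknown transform type: ", type, call. = FALSE)
  )
  storage.mode(lab) <- "integer"
  structure(list(image = img, label_map = lab,
                 has_tumor = any(lab == 2L),
                 tumor_count = sample$tumor_count),
            class = "phantom_sample")
}

#' Augment a phantom sample
#'
#' Draws from the plan under `seed`: each configured transform (every
#' rotation angle, each flip, one contrast draw, one scale draw) is
#' included independently with `apply_probability`. Returns the list of
#' augmented variants (the original is not included).
#'
#' @param sample a `phantom_sample`.
#' @param plan an [augmentation_plan()].
#' @param seed integer seed.
#' @return list of `phantom_sample` objects (possibly empty).
#' @export
augment <- function(sample, plan, seed = 1L) {
  stopifnot(inherits(plan, "augmentation_plan"))
  with_seed(seed, {
    out <- list()
    for (ang in plan$rotations) {
      if (runif(1) <= plan$apply_probability) {
        out[[length(out) + 1L]] <- transform_sample(sample, "rotate", ang)
      }
    }
    if (plan$hflip && runif(1) <= plan$apply_probability) {
      out[[length(out) + 1L]] <- transform_sample(sample, "hflip")
    }
    if (plan$vflip && runif(1) <= plan$apply_probability) {
      out[[length(out) + 1L]] <- transform_sample(sample, "vflip")
    }
    if (!is.null(plan$contrast_range) && runif(1) <= plan$apply_probability) {
      f <- runif(1, plan$contrast_range[1], plan$contrast_range[2])
      out[[length(out) + 1L]] <- transform_sample(sample, "contrast", f)
    }
    if (!is.null(plan$scale_range) && runif(1) <= plan$apply_probability) {
      f <- runif(1, plan$scale_range[1], plan$scale_range[2])
      out[[length(out) + 1L]] <- transform_sample(sample, "scale", f)
    }
    out
  })
}

#' Train/validation/test split ratios
#'
#' @param train,val,test fractions in `(0, 1)` summing to 1.
#' @return list of class `split_ratios`.
#' @export
split_ratios <- function(train = 0.7, val = 0.2, test = 0.1) {
  r <- c(train = train, val = val, test = test)
  if (any(r <= 0) || any(r >= 1)) stop("each fraction must lie in (0,1)", call. = FALSE)
  if (abs(sum(r) - 1) > 1e-9) stop("fractions must sum to 1", call. = FALSE)
  structure(as.list(r), class = "split_ratios")
}

#' Apportion n samples into train/val/test counts
#'
#' Largest-remainder apportionment of `n * ratio`, ties broken in favor
#' of later-listed splits; counts always sum to `n`.
#'
#' @param n total sample count (>= 3).
#' @param r a [split_ratios()].
#' @return named integer vector `(train, val, test)`.
#' @export
split_counts <- function(n, r = split_ratios()) {
  if (n < 3) stop("n must be >= 3", call. = FALSE)
  frac <- c(r$train, r$val, r$test)
  exact <- n * frac
  base <- floor(exact)
  rem <- as.integer(round(n - sum(base)))
  if (rem > 0) {
    # order by descending fractional part; ties go to later-listed splits
    ord <- order(exact - base, seq_along(frac), decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  stats::setNames(as.integer(base), c("train", "val", "test"))
}

#' Assign split labels to a manifest
#'
#' Rows are permuted under `seed` and assigned contiguously according to
#' [split_counts()]; the returned manifest keeps its original row order.
#'
#' @param manifest manifest data.frame.
#' @param r a [split_ratios()].
#' @param seed integer seed.
#' @return manifest with a filled `split` column.
#' @export
assign_splits <- function(manifest, r = split_ratios(), seed = 1L) {
  n <- nrow(manifest)
  if (n == 0) stop("manifest is empty", call. = FALSE)
  cnt <- split_counts(n, r)
  perm <- with_seed(seed, sample.int(n))
  lab <- rep(c("train", "val", "test"), times = cnt)
  manifest$split <- NA_character_
  manifest$split[perm] <- lab
  manifest
}
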