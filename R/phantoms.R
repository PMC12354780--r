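#' Specification for synthetic liver/tumor phantom slices
#'
#' Defines the study conditions for the built-in phantom generator: an
#' elliptical "liver" region on a darker background containing 0-3
#' brighter (or darker) "tumor" blobs, under additive Gaussian noise.
#' Tumor blobs are discs deformed by a low-frequency radial perturbation
#' (at most 20% of the radius) so that boundary-sensitive losses are
#' exercised on irregular shapes.
#'
#' @param height,width slice dimensions in pixels (>= 16).
#' @param liver_axes semi-axes `(a, b)` of the liver ellipse in pixels
#'   (row and column direction).
#' @param liver_center_jitter maximal uniform displacement of the liver
#'   center from the slice center, pixels.
#' @param n_tumors integer vector of admissible tumor counts, a subset of
#'   `0:3`; each sample draws its count uniformly from this set.
#' @param tumor_radius_range `(min, max)` nominal tumor radius, pixels.
#' @param tumor_contrast intensity delta of tumor over liver tissue, in
#'   `[-0.5, 0.5]`.
#' @param background_level,liver_level base intensities in `[0, 1]`.
#' @param noise_sd standard deviation of additive Gaussian noise
#'   (intensity units); intensities are clipped to `[0, 1]` afterwards.
#' @param rgb if `TRUE`, emit a 3-channel image: the grayscale channel
#'   duplicated and tinted by +5%/0%/-5% per channel.
#' @param seed integer seed; identical spec + seed gives bit-identical
#'   samples.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(height = 64, width = 64,
                         liver_axes = c(22, 16),
                         liver_center_jitter = 4,
                         n_tumors = 0:3,
                         tumor_radius_range = c(3, 7),
                         tumor_contrast = 0.3,
                         background_level = 0.2,
                         liver_level = 0.5,
                         noise_sd = 0.03,
                         rgb = FALSE,
                         seed = 1L) {
  spec <- list(height = as.integer(height), width = as.integer(width),
               liver_axes = as.numeric(liver_axes),
               liver_center_jitter = liver_center_jitter,
               n_tumors = as.integer(n_tumors),
               tumor_radius_range = as.numeric(tumor_radius_range),
               tumor_contrast = tumor_contrast,
               background_level = background_level,
               liver_level = liver_level,
               noise_sd = noise_sd, rgb = isTRUE(rgb),
               seed = as.integer(seed))
  class(spec) <- "phantom_spec"
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  if (spec$height < 16 || spec$width < 16) {
    stop("phantom dimensions must be at least 16 x 16", call. = FALSE)
  }
  if (!all(spec$n_tumors %in% 0:3)) {
    stop("n_tumors must be a subset of 0:3", call. = FALSE)
  }
  if (length(spec$tumor_radius_range) != 2 ||
      spec$tumor_radius_range[1] > spec$tumor_radius_range[2] ||
      spec$tumor_radius_range[1] < 1) {
    stop("tumor_radius_range must be (min, max) with min >= 1", call. = FALSE)
  }
  if (abs(spec$tumor_contrast) > 0.5) {
    stop("tumor_contrast must lie in [-0.5, 0.5]", call. = FALSE)
  }
  # Deformed blobs extend up to 1.2 * radius; they must fit strictly
  # inside the liver ellipse (infeasible geometry is rejected here).
  r_eff <- 1.2 * spec$tumor_radius_range[2]
  if (any(spec$n_tumors > 0) && r_eff >= min(spec$liver_axes)) {
    stop(sprintf(paste0("infeasible geometry: tumor radius %.1f ",
                        "(incl. 20%% deformation) cannot fit inside liver ",
                        "semi-axes (%.1f, %.1f)"),
                 r_eff, spec$liver_axes[1], spec$liver_axes[2]),
         call. = FALSE)
  }
  invisible(spec)
}

#' Generate one phantom sample
#'
#' Draws the liver ellipse, places `n_tumors` deformed-disc tumor blobs
#' entirely inside it, paints intensities (tumor pixels carry
#' `liver_level + tumor_contrast` before noise), adds Gaussian noise and
#' clips to `[0, 1]`.
#'
#' @param spec a [phantom_spec()].
#' @param seed optional seed override (defaults to `spec$seed`).
#' @return object of class `phantom_sample`: a list with `image`
#'   (matrix, or H x W x 3 array in RGB mode), `label_map` (integer
#'   matrix with 0 = background, 1 = liver, 2 = tumor), `has_tumor`,
#'   `tumor_count`.
#' @export
forge_sample <- function(spec, seed = spec$seed) {
  validate_phantom_spec(spec)
  with_seed(seed, {
    H <- spec$height; W <- spec$width
    a <- spec$liver_axes[1]; b <- spec$liver_axes[2]
    jit <- spec$liver_center_jitter
    ctr <- c((H + 1) / 2, (W + 1) / 2) + runif(2, -jit, jit)
    rr <- matrix(seq_len(H), H, W)
    cc <- matrix(seq_len(W), H, W, byrow = TRUE)
    liver <- ((rr - ctr[1]) / a)^2 + ((cc - ctr[2]) / b)^2 <= 1

    n_t <- if (length(spec$n_tumors) > 1) sample(spec$n_tumors, 1) else spec$n_tumors
    tumor <- matrix(FALSE, H, W)
    for (i in seq_len(n_t)) {
      r0 <- runif(1, spec$tumor_radius_range[1], spec$tumor_radius_range[2])
      r_eff <- 1.2 * r0
      # rejection-sample a center whose whole deformed blob fits in the ellipse
      repeat {
        dr <- runif(1, -(a - r_eff), a - r_eff)
        dc <- runif(1, -(b - r_eff), b - r_eff)
        if ((dr / (a - r_eff))^2 + (dc / (b - r_eff))^2 <= 1) break
      }
      tc <- ctr + c(dr, dc)
      # low-frequency radial perturbation, total amplitude <= 20% of r0
      amp <- runif(3, -1, 1)
      amp <- 0.2 * runif(1, 0.5, 1) * amp / sum(abs(amp))
      dy <- rr - tc[1]; dx <- cc - tc[2]
      theta <- atan2(dx, dy)
      rad <- r0 * (1 + amp[1] * cos(2 * theta + runif(1, 0, 2 * pi)) +
                     amp[2] * cos(3 * theta + runif(1, 0, 2 * pi)) +
                     amp[3] * cos(4 * theta + runif(1, 0, 2 * pi)))
      tumor <- tumor | (dy^2 + dx^2 <= rad^2)
    }
    tumor <- tumor & liver  # invariant: tumors lie inside the liver

    img <- matrix(spec$background_level, H, W)
    img[liver] <- spec$liver_level
    img[tumor] <- spec$liver_level + spec$tumor_contrast
    if (spec$noise_sd > 0) img <- img + matrix(rnorm(H * W, 0, spec$noise_sd), H, W)
    img <- clip01(img)
    if (spec$rgb) {
      img <- array(c(clip01(img * 1.05), img, clip01(img * 0.95)), dim = c(H, W, 3))
    }
    label <- matrix(0L, H, W)
    label[liver] <- 1L
    label[tumor] <- 2L
    structure(list(image = img, label_map = label,
                   has_tumor = any(label == 2L), tumor_count = n_t),
              class = "phantom_sample")
  })
}

#' Generate a phantom dataset on disk
#'
#' Writes `n` image/mask PNG pairs plus a `manifest.csv` (columns
#' `id, image_path, mask_path, has_tumor, split`). Sample `i` is seeded
#' with `spec$seed + i`, so regeneration with identical arguments is
#' bit-identical.
#'
#' @param spec a [phantom_spec()].
#' @param n number of samples (>= 1).
#' @param out_dir output directory (created if missing).
#' @return the manifest data.frame (invisibly carries its `root`).
#' @export
forge_dataset <- function(spec, n, out_dir) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  dir.create(file.path(out_dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  ids <- sprintf("s%04d", seq_len(n))
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    smp <- forge_sample(spec, seed = spec$seed + i)
    img_rel <- file.path("images", paste0(ids[i], ".png"))
    msk_rel <- file.path("masks", paste0(ids[i], ".png"))
    write_slice(smp$image, file.path(out_dir, img_rel))
    write_label_map(smp$label_map, file.path(out_dir, msk_rel))
    rows[[i]] <- data.frame(id = ids[i], image_path = img_rel,
                            mask_path = msk_rel, has_tumor = smp$has_tumor,
                            split = NA_character_,
                            stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  save_manifest(manifest, file.path(out_dir, "manifest.csv"))
  attr(manifest, "root") <- out_dir
  manifest
}
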