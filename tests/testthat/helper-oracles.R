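# Brute-force oracles, kept deliberately naive and independent of the
# package's implementations.

# bilateral filter: explicit double loop over all window pairs, window
# truncated at the border (same neighborhood definition as the filter)
oracle_bilateral <- function(img, sigma_s, sigma_r, r) {
  H <- nrow(img); W <- ncol(img)
  out <- matrix(0, H, W)
  for (x in seq_len(H)) {
    for (y in seq_len(W)) {
      num <- 0; den <- 0
      for (a in max(1, x - r):min(H, x + r)) {
        for (b in max(1, y - r):min(W, y + r)) {
          ws <- exp(-((a - x)^2 + (b - y)^2) / (2 * sigma_s^2))
          wr <- exp(-((img[a, b] - img[x, y])^2) / (2 * sigma_r^2))
          num <- num + img[a, b] * ws * wr
          den <- den + ws * wr
        }
      }
      out[x, y] <- num / den
    }
  }
  out
}

# symmetric Hausdorff distance by all-pairs enumeration
oracle_hausdorff <- function(A, B) {
  pa <- which(A != 0, arr.ind = TRUE)
  pb <- which(B != 0, arr.ind = TRUE)
  dmat <- sqrt(outer(pa[, 1], pb[, 1], "-")^2 + outer(pa[, 2], pb[, 2], "-")^2)
  max(max(apply(dmat, 1, min)), max(apply(dmat, 2, min)))
}

# confusion counts by an explicit pixel loop
oracle_confusion <- function(pred, target) {
  tp <- fp <- tn <- fn <- 0
  for (i in seq_along(pred)) {
    if (pred[i] == 1 && target[i] == 1) tp <- tp + 1
    if (pred[i] == 1 && target[i] == 0) fp <- fp + 1
    if (pred[i] == 0 && target[i] == 0) tn <- tn + 1
    if (pred[i] == 0 && target[i] == 1) fn <- fn + 1
  }
  c(tp = tp, fp = fp, tn = tn, fn = fn)
}

# random connected-ish blob mask with <= max_pts foreground points
random_mask <- function(H, W, n_blobs = 2, rmax = 5) {
  m <- matrix(0, H, W)
  for (i in seq_len(n_blobs)) {
    cy <- sample(seq_len(H), 1); cx <- sample(seq_len(W), 1)
    r <- runif(1, 1, rmax)
    yy <- matrix(seq_len(H), H, W); xx <- matrix(seq_len(W), H, W, byrow = TRUE)
    m[(yy - cy)^2 + (xx - cx)^2 <= r^2] <- 1
  }
  m
}

# small phantom spec used across tests (geometry scaled to the size)
tiny_spec <- function(size = 32, seed = 1L, ...) {
  phantom_spec(height = size, width = size,
               liver_axes = c(size * 0.32, size * 0.25),
               liver_center_jitter = size / 16,
               tumor_radius_range = c(max(1.5, size / 21), size / 10),
               seed = seed, ...)
}

# deterministic micro-manifest for harness tests (no files involved)
fake_manifest <- function(n, n_tumor = round(0.75 * n)) {
  data.frame(id = sprintf("s%04d", seq_len(n)),
             image_path = NA_character_, mask_path = NA_character_,
             has_tumor = rep(c(TRUE, FALSE), c(n_tumor, n - n_tumor)),
             split = NA_character_, stringsAsFactors = FALSE)
}
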