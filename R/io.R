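#' Read an image slice from a PNG file
#'
#' Returns a numeric matrix (grayscale) or an H x W x 3 array (RGB) with
#' intensities in `[0, 1]`. Alpha channels are dropped.
#'
#' @param path path to a PNG file.
#' @return numeric matrix or 3-channel array.
#' @export
read_slice <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path, call. = FALSE)
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) {
    if (dim(img)[3] >= 3L) img <- img[, , 1:3, drop = FALSE] else img <- img[, , 1]
  }
  img
}

#' Write an image slice to an 8-bit PNG file
#'
#' Intensities are clipped to `[0, 1]` and quantized to 8 bits on write.
#'
#' @param img numeric matrix or H x W x 3 array in `[0, 1]`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_slice <- function(img, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  png::writePNG(clip01(img), path)
  invisible(path)
}

#' Read a label map from a PNG file
#'
#' Label maps are stored with raw class ids (0 = background, 1 = liver,
#' 2 = tumor) in an 8-bit PNG, i.e. pixel value `id/255`.
#'
#' @param path path to a mask PNG.
#' @return integer matrix of class ids.
#' @export
read_label_map <- function(path) {
  if (!file.exists(path)) stop("mask file not found: ", path, call. = FALSE)
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  lab <- round(m * 255)
  storage.mode(lab) <- "integer"
  lab
}

#' Write a label map to an 8-bit PNG file
#'
#' @param label_map integer matrix of class ids (0..255).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_label_map <- function(label_map, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  png::writePNG(label_map / 255, path)
  invisible(path)
}

#' Load a dataset manifest CSV
#'
#' The manifest indexes image/mask pairs with columns
#' `id, image_path, mask_path, has_tumor` and optionally `split`. Paths
#' are stored relative to the manifest's directory, which is attached as
#' the `root` attribute so downstream loaders can resolve them.
#'
#' @param path path to `manifest.csv`.
#' @return data.frame with attribute `root`.
#' @export
load_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path, call. = FALSE)
  man <- utils::read.csv(path, stringsAsFactors = FALSE)
  attr(man, "root") <- dirname(path)
  man
}

#' @rdname load_manifest
#' @param manifest manifest data.frame.
#' @export
save_manifest <- function(manifest, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  keep <- setdiff(names(manifest), character(0))
  utils::write.csv(manifest[keep], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Resolve a manifest-relative path against the manifest root.
manifest_path <- function(manifest, rel) {
  root <- attr(manifest, "root")
  if (is.null(root)) rel else file.path(root, rel)
}
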