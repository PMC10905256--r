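# Raster conventions used throughout the package:
#   images and masks are plain numeric/integer matrices, row = y
#   (increasing downward), column = x; pixel (y, x) is matrix[y + 1, x + 1]
#   (coordinates are 0-based, matrix indices 1-based).

#' Read a grayscale image (TIFF or PNG)
#'
#' Returns the image as a numeric matrix with rows = image rows (y) and
#' columns = x.  Multi-channel files are collapsed to grayscale by
#' averaging channels.
#'
#' @param path Path to a `.tif`/`.tiff` or `.png` file.
#' @return Numeric matrix of intensities.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path)
  img <- switch(tolower(tools::file_ext(path)),
    "tif"  = tiff::readTIFF(path),
    "tiff" = tiff::readTIFF(path),
    "png"  = png::readPNG(path),
    stop("unsupported image format: ", path)
  )
  if (length(dim(img)) == 3L) img <- apply(img, c(1L, 2L), mean)
  validate_image(img)
  img
}

#' Write a grayscale image (TIFF or PNG)
#'
#' Intensities are rescaled to `[0, 1]` (by the image maximum, unless the
#' image is already within range) before writing.
#'
#' @param image Numeric matrix.
#' @param path Output path ending in `.tif`/`.tiff` or `.png`.
#' @param bits Bits per sample (8, 16 or 32).
#' @return Invisibly, `path`.
#' @export
write_image <- function(image, path, bits = 16L) {
  validate_image(image)
  mx <- max(image)
  if (mx > 1 || min(image) < 0) image <- (image - min(image)) / max(mx - min(image), .Machine$double.eps)
  ok <- switch(tolower(tools::file_ext(path)),
    "tif"  = tiff::writeTIFF(image, path, bits.per.sample = bits),
    "tiff" = tiff::writeTIFF(image, path, bits.per.sample = bits),
    "png"  = png::writePNG(image, path),
    stop("unsupported image format: ", path)
  )
  invisible(path)
}

#' Write an integer label mask as a 16-bit single-channel TIFF
#'
#' Labels are stored exactly (as `label / 65535`), so masks with at most
#' 65535 cells round-trip losslessly through [read_mask()].
#'
#' @param mask Integer matrix, 0 = background.
#' @param path Output `.tif` path.
#' @return Invisibly, `path`.
#' @export
write_mask <- function(mask, path) {
  validate_mask(mask)
  if (max(mask) > 65535L) stop("mask has more than 65535 labels; cannot store as 16-bit TIFF")
  tiff::writeTIFF(mask / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read an integer label mask written by [write_mask()]
#'
#' Also accepts plain binary (0/255-style) mask images, which decode to
#' labels 0/1 after connected-component relabelling is left to the caller.
#'
#' @param path Path to the mask TIFF/PNG.
#' @return Integer matrix of labels.
#' @export
read_mask <- function(path) {
  img <- read_image(path)
  m <- matrix(as.integer(round(img * 65535)), nrow(img), ncol(img))
  m
}

validate_image <- function(image) {
  if (!is.matrix(image) || !is.numeric(image)) stop("image must be a numeric matrix")
  if (nrow(image) < 1L || ncol(image) < 1L) stop("image must be non-empty")
  if (!all(is.finite(image))) stop("image intensities must be finite")
  invisible(image)
}

validate_mask <- function(mask) {
  if (!is.matrix(mask) || !is.numeric(mask)) stop("mask must be an integer matrix")
  if (any(mask < 0)) stop("mask labels must be nonnegative")
  if (any(mask != round(mask))) stop("mask labels must be integers")
  invisible(mask)
}

#' Compact mask labels to 1..K
#'
#' Renames the nonzero labels of a mask to consecutive integers
#' `1..K`, preserving their numeric order.  The pixel partition is
#' unchanged.
#'
#' @param mask Integer label matrix.
#' @return Relabelled integer matrix.
#' @export
compact_labels <- function(mask) {
  validate_mask(mask)
  labs <- sort(unique(mask[mask > 0]))
  if (length(labs) == 0L) return(matrix(0L, nrow(mask), ncol(mask)))
  lut <- integer(max(labs) + 1L)        # lut[label + 1] -> new label
  lut[labs + 1L] <- seq_along(labs)
  out <- matrix(lut[mask + 1L], nrow(mask), ncol(mask))
  out
}

# circularly shift a matrix: result[y, x] = m[y - dy, x - dx] (wrapped)
shift_mat <- function(m, dy, dx) {
  h <- nrow(m); w <- ncol(m)
  dy <- ((dy %% h) + h) %% h
  dx <- ((dx %% w) + w) %% w
  ri <- ((seq_len(h) - 1 - dy) %% h) + 1
  ci <- ((seq_len(w) - 1 - dx) %% w) + 1
  m[ri, ci, drop = FALSE]
}

# per-label areas and centroids (0-based y/x) of a mask
mask_regions <- function(mask) {
  idx <- which(mask > 0)
  if (length(idx) == 0L)
    return(data.frame(label = integer(), area_px = integer(),
                      centroid_y = numeric(), centroid_x = numeric()))
  lab <- mask[idx]
  y <- (idx - 1L) %% nrow(mask)
  x <- (idx - 1L) %/% nrow(mask)
  dt <- data.table::data.table(label = lab, y = y, x = x)
  out <- dt[, list(area_px = .N, centroid_y = mean(y), centroid_x = mean(x)),
            by = "label"]
  data.table::setorder(out, label)
  as.data.frame(out)
}
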