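#' Construct an image grid
#'
#' An `image_grid` is the package's in-memory raster: a matrix of integer
#' gray levels plus the bit depth and the physical calibration needed to
#' convert pixel counts into mm^2. Pixels are stored as `pixels[row, col]`
#' with the origin at the top-left; user-facing coordinates are 0-based
#' `(x = column, y = row)`.
#'
#' @param pixels integer matrix of intensities, all in `[0, 2^bit_depth - 1]`.
#' @param bit_depth 8 or 16.
#' @param calibration_um_per_px micrometres spanned by one pixel edge (> 0).
#' @return An object of class `image_grid` with fields `pixels`, `bit_depth`,
#'   `height`, `width`, `calibration_um_per_px`.
#' @export
image_grid <- function(pixels, bit_depth = 8L, calibration_um_per_px = 1) {
  if (!is.matrix(pixels)) stop("pixels must be a matrix")
  storage.mode(pixels) <- "integer"
  bit_depth <- as.integer(bit_depth)
  if (!bit_depth %in% c(8L, 16L)) stop("bit_depth must be 8 or 16")
  if (anyNA(pixels)) stop("pixels must not contain NA")
  maxv <- 2L^bit_depth - 1L
  if (min(pixels) < 0L || max(pixels) > maxv)
    stop(sprintf("intensities must lie in [0, %d] for bit depth %d", maxv, bit_depth))
  if (!is.numeric(calibration_um_per_px) || length(calibration_um_per_px) != 1L ||
      !is.finite(calibration_um_per_px) || calibration_um_per_px <= 0)
    stop("calibration_um_per_px must be a single finite positive number")
  structure(
    list(pixels = pixels, bit_depth = bit_depth,
         height = nrow(pixels), width = ncol(pixels),
         calibration_um_per_px = as.numeric(calibration_um_per_px)),
    class = "image_grid"
  )
}

#' @export
print.image_grid <- function(x, ...) {
  cat(sprintf("<image_grid> %d x %d px, %d-bit, %.4g um/px, intensities [%d, %d]\n",
              x$width, x$height, x$bit_depth, x$calibration_um_per_px,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Construct a binary region mask
#'
#' A `region_mask` marks a pixel set (explant body, sprouts, keep-region) on
#' the same grid as its source image.
#'
#' @param bits logical matrix (TRUE = member pixel).
#' @return An object of class `region_mask` with fields `bits`, `height`,
#'   `width`, `pixel_count`.
#' @export
region_mask <- function(bits) {
  if (!is.matrix(bits) || !is.logical(bits)) stop("bits must be a logical matrix")
  if (anyNA(bits)) stop("mask must not contain NA")
  structure(
    list(bits = bits, height = nrow(bits), width = ncol(bits),
         pixel_count = sum(bits)),
    class = "region_mask"
  )
}

#' @export
print.region_mask <- function(x, ...) {
  cat(sprintf("<region_mask> %d x %d px, %d set\n", x$width, x$height, x$pixel_count))
  invisible(x)
}

#' Measure a mask's area in pixels and mm^2
#'
#' `mm2 = pixels * (calibration_um_per_px / 1000)^2`: a pixel is a square of
#' side `calibration_um_per_px` micrometres.
#'
#' @param mask a [region_mask()].
#' @param calibration_um_per_px micrometres per pixel edge (> 0).
#' @return An `area_measure`: list with `pixels` (integer) and `mm2` (numeric).
#' @export
measure_area <- function(mask, calibration_um_per_px) {
  stopifnot(inherits(mask, "region_mask"))
  if (!is.numeric(calibration_um_per_px) || length(calibration_um_per_px) != 1L ||
      !is.finite(calibration_um_per_px) || calibration_um_per_px <= 0)
    stop("calibration_um_per_px must be a single finite positive number")
  area_measure(mask$pixel_count, calibration_um_per_px)
}

area_measure <- function(pixels, calibration_um_per_px) {
  structure(
    list(pixels = as.integer(pixels),
         mm2 = pixels * (calibration_um_per_px / 1000)^2),
    class = "area_measure"
  )
}

#' @export
print.area_measure <- function(x, ...) {
  cat(sprintf("<area> %d px = %.6g mm^2\n", x$pixels, x$mm2))
  invisible(x)
}

# shared guard: mask dimensions must match the image's
check_same_dims <- function(image, mask, what = "mask") {
  if (mask$height != image$height || mask$width != image$width)
    stop(sprintf("%s dimensions (%d x %d) do not match image (%d x %d)",
                 what, mask$width, mask$height, image$width, image$height))
  invisible(TRUE)
}

# 0-based (x, y) -> validated 1-based (row, col)
seed_to_rc <- function(image, seed) {
  if (length(seed) != 2L || anyNA(seed)) stop("seed must be c(x, y)")
  x <- as.integer(seed[[1L]]); y <- as.integer(seed[[2L]])
  if (x < 0L || x >= image$width || y < 0L || y >= image$height)
    stop(sprintf("seed (%d, %d) out of bounds for %d x %d image",
                 x, y, image$width, image$height))
  c(row = y + 1L, col = x + 1L)
}
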