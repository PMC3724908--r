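#' Load a grayscale image with physical calibration
#'
#' Reads an 8- or 16-bit single-channel TIFF or PNG into an [image_grid()].
#' Pixel values are returned exactly as stored — no rescaling, no gamma.
#' Multi-channel rasters are accepted only when all channels are identical
#' (a grayscale image saved as RGB); anything else is rejected because
#' phase-contrast source data is single-channel.
#'
#' @param path path to a `.tif`/`.tiff` or `.png` file.
#' @param calibration_um_per_px micrometres per pixel edge (> 0).
#' @return An [image_grid()].
#' @export
load_image <- function(path, calibration_um_per_px = 1) {
  if (!file.exists(path)) stop(sprintf("image file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    raw <- tiff::readTIFF(path, as.is = TRUE, info = TRUE)
    bits <- attr(raw, "bits.per.sample")
    if (is.null(bits)) bits <- 8L
    arr <- unclass(raw)
    attributes(arr) <- list(dim = dim(raw))
  } else if (ext == "png") {
    raw <- png::readPNG(path, info = TRUE)
    bits <- attr(raw, "info")$bit.depth
    arr <- round(unclass(raw) * (2^bits - 1))
    attributes(arr) <- list(dim = dim(raw))
  } else {
    stop(sprintf("unsupported image format '%s' for %s (use TIFF or PNG)", ext, path))
  }
  if (!bits %in% c(8, 16))
    stop(sprintf("unsupported bit depth %s in %s", bits, path))
  if (length(dim(arr)) == 3L) {
    ch1 <- arr[, , 1L]
    for (k in seq_len(dim(arr)[3L])[-1L]) {
      if (!identical(as.vector(arr[, , k]), as.vector(ch1)))
        stop(sprintf("%s is multi-channel with non-identical channels; expected grayscale", path))
    }
    arr <- ch1
  }
  img <- image_grid(matrix(as.integer(arr), nrow(arr), ncol(arr)),
                    bit_depth = as.integer(bits),
                    calibration_um_per_px = calibration_um_per_px)
  attr(img, "source_path") <- path
  img
}

#' Save an image grid to disk
#'
#' Writes TIFF at the image's own bit depth (8 or 16) and PNG at 8 bits
#' (16-bit PNG is supported for reading only). Round trips through
#' [load_image()] are lossless at matching depth.
#'
#' @param image an [image_grid()].
#' @param path output path ending in `.tif`, `.tiff` or `.png`.
#' @return `path`, invisibly.
#' @export
save_image <- function(image, path) {
  stopifnot(inherits(image, "image_grid"))
  maxv <- 2^image$bit_depth - 1
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(image$pixels / maxv, path, bits.per.sample = image$bit_depth)
  } else if (ext == "png") {
    if (image$bit_depth != 8L)
      stop("PNG output is 8-bit only; save 16-bit images as TIFF")
    png::writePNG(image$pixels / maxv, path)
  } else {
    stop(sprintf("unsupported output format '%s' (use TIFF or PNG)", ext))
  }
  invisible(path)
}

#' Write a QC overlay of the segmentation
#'
#' Renders the grayscale image with the explant region tinted blue and the
#' sprout region tinted red, as an 8-bit RGB PNG. With both masks empty the
#' overlay is the grayscale base replicated to three channels.
#'
#' @param image an [image_grid()].
#' @param explant,sprouts [region_mask()]s matching the image dimensions.
#' @param out_path output path; default is the conventional
#'   `<image>_swift_overlay.png` beside the source when `image` carries a
#'   `source_path` attribute, otherwise required.
#' @param alpha tint strength in `[0, 1]`.
#' @return `out_path`, invisibly.
#' @export
save_overlay <- function(image, explant, sprouts, out_path = NULL, alpha = 0.45) {
  stopifnot(inherits(image, "image_grid"),
            inherits(explant, "region_mask"), inherits(sprouts, "region_mask"))
  check_same_dims(image, explant, "explant mask")
  check_same_dims(image, sprouts, "sprout mask")
  if (is.null(out_path)) {
    src <- attr(image, "source_path")
    if (is.null(src)) stop("out_path required when the image has no source path")
    out_path <- file.path(dirname(src),
                          paste0(tools::file_path_sans_ext(basename(src)),
                                 "_swift_overlay.png"))
  }
  base <- image$pixels / (2^image$bit_depth - 1)
  rgb <- array(base, dim = c(image$height, image$width, 3L))
  # explant: blue tint; sprouts: red tint
  tint <- function(rgb, bits, col) {
    for (k in 1:3) {
      ch <- rgb[, , k]
      ch[bits] <- (1 - alpha) * ch[bits] + alpha * col[k]
      rgb[, , k] <- ch
    }
    rgb
  }
  rgb <- tint(rgb, explant$bits, c(0.15, 0.35, 1))
  rgb <- tint(rgb, sprouts$bits, c(1, 0.15, 0.15))
  dir <- dirname(out_path)
  if (!dir.exists(dir)) stop(sprintf("output directory does not exist: %s", dir))
  png::writePNG(rgb, out_path)
  invisible(out_path)
}

manifest_required_cols <- c("sample_id", "image_path", "seed_x", "seed_y",
                            "group", "batch", "calibration_um_per_px")

#' Load an experiment manifest
#'
#' The manifest is a CSV assigning each image to a sample, group and batch,
#' with its wand seed point and µm-per-pixel calibration. Required columns:
#' `sample_id, image_path, seed_x, seed_y, group, batch, calibration_um_per_px`;
#' an optional `roi_path` column points at keep-region polygon files. Extra
#' columns are preserved but ignored.
#'
#' @param path CSV path.
#' @return A data.frame of class `experiment_manifest`.
#' @export
load_manifest <- function(path) {
  if (!file.exists(path)) stop(sprintf("manifest not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(manifest_required_cols, names(df))
  if (length(missing))
    stop(sprintf("manifest is missing required column(s): %s",
                 paste(missing, collapse = ", ")))
  if (!"roi_path" %in% names(df)) df$roi_path <- NA_character_
  df$roi_path[!is.na(df$roi_path) & !nzchar(df$roi_path)] <- NA_character_
  for (col in c("seed_x", "seed_y", "calibration_um_per_px")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (anyNA(v)) stop(sprintf("manifest column '%s' contains non-numeric values", col))
    df[[col]] <- v
  }
  if (any(df$calibration_um_per_px <= 0))
    stop("calibration_um_per_px must be positive for every sample")
  dup <- unique(df$sample_id[duplicated(df$sample_id)])
  if (length(dup))
    stop(sprintf("duplicate sample_id in manifest: %s", paste(dup, collapse = ", ")))
  df$sample_id <- as.character(df$sample_id)
  df$group <- as.character(df$group)
  df$batch <- as.character(df$batch)
  class(df) <- c("experiment_manifest", "data.frame")
  df
}

#' Write an experiment manifest CSV
#' @param manifest a data.frame with the manifest columns.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(as.data.frame(manifest), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
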