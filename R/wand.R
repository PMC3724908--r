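#' Seeded region growing ("magic wand") selection
#'
#' Deterministic re-implementation of the interactive magic-wand selection
#' used to outline the explant body: the maximal 8-connected region
#' containing the seed in which every pixel's intensity `v` satisfies
#' `|v - v_seed| <= tolerance_fraction * (2^bit_depth - 1)`.
#'
#' The reference value is the seed pixel itself (optionally the median of
#' its 3x3 neighbourhood), never a moving reference, so the result is a
#' fixed set independent of traversal order. The default tolerance of 0.30
#' is the fraction of the full dynamic range conventionally used for this
#' assay.
#'
#' @param image an [image_grid()].
#' @param seed `c(x, y)` 0-based pixel coordinates inside the image.
#' @param tolerance_fraction number in `[0, 1]`: half-width of the intensity
#'   window as a fraction of the full dynamic range.
#' @param seed_median_3x3 if TRUE, the reference intensity is the median of
#'   the in-bounds 3x3 neighbourhood around the seed (robust to a single
#'   noisy seed pixel); default FALSE.
#' @return A [region_mask()]; the seed pixel is always a member.
#' @export
magic_wand <- function(image, seed, tolerance_fraction = 0.30,
                       seed_median_3x3 = FALSE) {
  stopifnot(inherits(image, "image_grid"))
  rc <- seed_to_rc(image, seed)
  if (!is.numeric(tolerance_fraction) || length(tolerance_fraction) != 1L ||
      !is.finite(tolerance_fraction))
    stop("tolerance_fraction must be a single finite number")
  if (tolerance_fraction < 0 || tolerance_fraction > 1)
    stop("tolerance_fraction must lie in [0, 1]")
  px <- image$pixels
  if (seed_median_3x3) {
    rows <- max(1L, rc["row"] - 1L):min(image$height, rc["row"] + 1L)
    cols <- max(1L, rc["col"] - 1L):min(image$width, rc["col"] + 1L)
    ref <- stats::median(px[rows, cols])
  } else {
    ref <- px[rc["row"], rc["col"]]
  }
  halfwidth <- tolerance_fraction * (2^image$bit_depth - 1)
  eligible <- abs(px - ref) <= halfwidth
  # the seed is in-window by construction (|v_seed - ref| = 0 unless median
  # reference shifts it); force membership per the selection contract
  eligible[rc["row"], rc["col"]] <- TRUE
  bits <- .flood_fill_cpp(eligible, rc["row"] - 1L, rc["col"] - 1L, TRUE)
  region_mask(bits)
}

#' Fill enclosed holes in a mask
#'
#' Adds to the mask every background component that is not 4-connected to
#' the image border, making the explant region simply connected so interior
#' bright pixels are never later counted as sprouts. Set pixels are never
#' removed.
#'
#' @param mask a [region_mask()].
#' @return A [region_mask()] with holes filled.
#' @export
fill_holes <- function(mask) {
  stopifnot(inherits(mask, "region_mask"))
  bg <- !mask$bits
  nr <- mask$height; nc <- mask$width
  # seeds: every border pixel (0-based); flood 4-connected over background
  border_r <- c(rep(0L, nc), rep(nr - 1L, nc), seq_len(nr) - 1L, seq_len(nr) - 1L)
  border_c <- c(seq_len(nc) - 1L, seq_len(nc) - 1L, rep(0L, nr), rep(nc - 1L, nr))
  outside <- .flood_fill_cpp(bg, border_r, border_c, FALSE)
  region_mask(mask$bits | (bg & !outside))
}
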