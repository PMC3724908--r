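#' Construct a polygon region of interest
#'
#' Polygons are ordered vertex lists in 0-based pixel coordinates. They must
#' be simple (non-self-intersecting) with strictly positive shoelace area.
#' Used both as keep-regions for background exclusion and as the total
#' sprout outline of the manual quantification method.
#'
#' @param vertices numeric matrix or data.frame with two columns `(x, y)`,
#'   at least 3 rows.
#' @return An object of class `polygon_roi` with fields `x`, `y`, `area`
#'   (shoelace, in squared pixels).
#' @export
polygon_roi <- function(vertices) {
  v <- as.matrix(vertices)
  if (ncol(v) != 2L || nrow(v) < 3L)
    stop("a polygon needs >= 3 (x, y) vertices")
  if (anyNA(v) || !all(is.finite(v))) stop("polygon vertices must be finite")
  x <- as.numeric(v[, 1L]); y <- as.numeric(v[, 2L])
  n <- length(x)
  j <- c(2:n, 1L)
  area <- abs(sum(x * y[j] - x[j] * y)) / 2
  if (area <= 0) stop("polygon has zero area")
  if (.polygon_self_intersects(x, y)) stop("polygon is self-intersecting")
  structure(list(x = x, y = y, area = area), class = "polygon_roi")
}

# proper-crossing test between all non-adjacent edge pairs
.polygon_self_intersects <- function(x, y) {
  n <- length(x)
  seg <- cbind(x, y, x[c(2:n, 1L)], y[c(2:n, 1L)])
  cross <- function(ox, oy, ax, ay, bx, by) (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  for (i in seq_len(n - 2L)) {
    jmax <- if (i == 1L) n - 1L else n
    for (j in (i + 2L):jmax) {
      d1 <- cross(seg[i, 1], seg[i, 2], seg[i, 3], seg[i, 4], seg[j, 1], seg[j, 2])
      d2 <- cross(seg[i, 1], seg[i, 2], seg[i, 3], seg[i, 4], seg[j, 3], seg[j, 4])
      d3 <- cross(seg[j, 1], seg[j, 2], seg[j, 3], seg[j, 4], seg[i, 1], seg[i, 2])
      d4 <- cross(seg[j, 1], seg[j, 2], seg[j, 3], seg[j, 4], seg[i, 3], seg[i, 4])
      if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
          ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(TRUE)
    }
  }
  FALSE
}

#' Read a polygon ROI from a JSON file
#'
#' Format: `{"format": "sproutquant-roi-1", "vertices": [[x, y], ...]}`.
#' @param path JSON file path.
#' @return A [polygon_roi()].
#' @export
load_roi <- function(path) {
  if (!file.exists(path)) stop(sprintf("ROI file not found: %s", path))
  obj <- jsonlite::fromJSON(path)
  if (is.null(obj$vertices)) stop(sprintf("no 'vertices' field in %s", path))
  polygon_roi(obj$vertices)
}

#' Write a polygon ROI to a JSON file
#' @param roi a [polygon_roi()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_roi <- function(roi, path) {
  stopifnot(inherits(roi, "polygon_roi"))
  jsonlite::write_json(
    list(format = "sproutquant-roi-1",
         vertices = unname(cbind(roi$x, roi$y))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Even-odd point-in-polygon test
#'
#' Crossing-number rule; points exactly on the boundary count as inside
#' (inclusive convention, so an axis-aligned rectangle whose edges pass
#' through pixel centers keeps those pixels).
#'
#' @param px,py numeric vectors of point coordinates.
#' @param poly a [polygon_roi()].
#' @return Logical vector.
#' @export
points_in_polygon <- function(px, py, poly) {
  stopifnot(inherits(poly, "polygon_roi"))
  x <- poly$x; y <- poly$y
  n <- length(x)
  j <- c(2:n, 1L)
  inside <- rep(FALSE, length(px))
  onedge <- rep(FALSE, length(px))
  eps <- 1e-9
  for (k in seq_len(n)) {
    x1 <- x[k]; y1 <- y[k]; x2 <- x[j[k]]; y2 <- y[j[k]]
    crosses <- ((y1 > py) != (y2 > py)) &
      (px < x1 + (py - y1) * (x2 - x1) / (y2 - y1))
    crosses[is.na(crosses)] <- FALSE
    inside <- xor(inside, crosses)
    # on-segment: collinear and within the bounding box
    d <- (x2 - x1) * (py - y1) - (y2 - y1) * (px - x1)
    len <- sqrt((x2 - x1)^2 + (y2 - y1)^2)
    on <- abs(d) <= eps * max(1, len) &
      px >= pmin(x1, x2) - eps & px <= pmax(x1, x2) + eps &
      py >= pmin(y1, y2) - eps & py <= pmax(y1, y2) + eps
    onedge <- onedge | on
  }
  inside | onedge
}

#' Rasterize a polygon to a pixel mask
#'
#' A pixel `(x, y)` (0-based) is set when its center lies inside the polygon
#' under the inclusive even-odd rule of [points_in_polygon()], making polygon
#' areas commensurable with mask areas.
#'
#' @param poly a [polygon_roi()].
#' @param height,width canvas dimensions in pixels.
#' @return A [region_mask()].
#' @export
rasterize_polygon <- function(poly, height, width) {
  stopifnot(inherits(poly, "polygon_roi"))
  bits <- matrix(FALSE, height, width)
  # restrict the test to the polygon's bounding box
  cx <- max(0L, floor(min(poly$x))):min(width - 1L, ceiling(max(poly$x)))
  cy <- max(0L, floor(min(poly$y))):min(height - 1L, ceiling(max(poly$y)))
  if (length(cx) == 0L || length(cy) == 0L) return(region_mask(bits))
  grid <- expand.grid(y = cy, x = cx)
  hit <- points_in_polygon(grid$x, grid$y, poly)
  bits[cbind(grid$y + 1L, grid$x + 1L)] <- hit
  region_mask(bits)
}

#' Delete the explant body from an image
#'
#' Replaces every explant pixel with the modal intensity of the remaining
#' pixels (the histogram mode of the non-mask region; ties broken toward the
#' lower gray level), so the deletion leaves no spurious dark class to bias
#' a subsequent automatic threshold. The explant mask should be hole-filled
#' by the caller ([swift_quantify()] does this); `delete_explant` uses the
#' mask exactly as given.
#'
#' @param image an [image_grid()].
#' @param explant a [region_mask()] matching the image.
#' @return List with `image` (modified copy; the input is untouched) and
#'   `area` (the explant [measure_area()] at the image's calibration).
#' @export
delete_explant <- function(image, explant) {
  stopifnot(inherits(image, "image_grid"))
  stopifnot(inherits(explant, "region_mask"))
  check_same_dims(image, explant, "explant mask")
  if (explant$pixel_count == prod(dim(explant$bits)))
    stop("explant mask covers the entire image; nothing left to threshold")
  px <- image$pixels
  if (explant$pixel_count > 0L) {
    counts <- tabulate(px[!explant$bits] + 1L, nbins = 2L^image$bit_depth)
    mode_val <- which.max(counts) - 1L
    px[explant$bits] <- mode_val
  }
  list(image = image_grid(px, image$bit_depth, image$calibration_um_per_px),
       area = measure_area(explant, image$calibration_um_per_px))
}

#' Otsu threshold of an image histogram
#'
#' Exhaustive search over every candidate threshold `t` in
#' `0 .. 2^bit_depth - 2` maximizing the between-class variance of the split
#' `{v <= t} / {v > t}`; ties resolved toward the smallest `t`. Deterministic.
#'
#' @param image an [image_grid()].
#' @return Integer threshold.
#' @export
otsu_threshold <- function(image) {
  stopifnot(inherits(image, "image_grid"))
  L <- 2L^image$bit_depth
  counts <- tabulate(image$pixels + 1L, nbins = L)
  if (sum(counts > 0L) < 2L)
    stop("degenerate histogram: image has a single gray level")
  p <- counts / sum(counts)
  levels <- 0:(L - 1)
  omega <- cumsum(p)              # P(v <= t), t = 0 .. L-1
  mu <- cumsum(p * levels)        # E[v; v <= t]
  mu_t <- mu[L]
  t_all <- seq_len(L - 1L)        # candidate t = 0 .. L-2 (index t+1)
  w <- omega[t_all]
  valid <- w > 0 & w < 1
  sigma_b <- rep(-Inf, L - 1L)
  sigma_b[valid] <- (mu_t * w[valid] - mu[t_all][valid])^2 /
    (w[valid] * (1 - w[valid]))
  as.integer(which.max(sigma_b) - 1L)
}

#' Threshold the post-deletion image to isolate sprouts
#'
#' Binarizes the image at an automatic (Otsu) or fixed gray level. With
#' `polarity = "dark_objects"` (phase-contrast sprouts are darker than the
#' background halo) the mask is `v <= threshold`; with `"bright_objects"` it
#' is `v > threshold` — exact complements.
#'
#' @param image an [image_grid()] (normally the explant-deleted image).
#' @param method `"otsu"` or `"fixed"`.
#' @param fixed_value gray level for `method = "fixed"`.
#' @param polarity `"dark_objects"` (default) or `"bright_objects"`.
#' @return List with `mask` (a [region_mask()]) and `threshold_used`
#'   (integer gray level).
#' @export
threshold_sprouts <- function(image, method = c("otsu", "fixed"),
                              fixed_value = NULL,
                              polarity = c("dark_objects", "bright_objects")) {
  stopifnot(inherits(image, "image_grid"))
  method <- match.arg(method)
  polarity <- match.arg(polarity)
  if (method == "fixed") {
    if (is.null(fixed_value)) stop("fixed_value required for method = 'fixed'")
    fixed_value <- as.integer(fixed_value)
    if (fixed_value < 0L || fixed_value > 2L^image$bit_depth - 1L)
      stop(sprintf("fixed_value %d out of range for %d-bit image",
                   fixed_value, image$bit_depth))
    thr <- fixed_value
  } else {
    thr <- otsu_threshold(image)
  }
  bits <- if (polarity == "dark_objects") image$pixels <= thr else image$pixels > thr
  list(mask = region_mask(bits), threshold_used = thr)
}

#' Clear mask pixels outside a keep-region
#'
#' Reproduces the free-selection background removal step: with a keep
#' polygon, sprout-mask pixels whose centers fall outside it are cleared;
#' without one the mask passes through unchanged. Vertices outside the
#' image bounds are clipped to the border with a warning.
#'
#' @param mask a [region_mask()].
#' @param keep optional [polygon_roi()].
#' @return A [region_mask()].
#' @export
exclude_background <- function(mask, keep = NULL) {
  stopifnot(inherits(mask, "region_mask"))
  if (is.null(keep)) return(mask)
  stopifnot(inherits(keep, "polygon_roi"))
  x <- keep$x; y <- keep$y
  if (any(x < 0 | x > mask$width - 1 | y < 0 | y > mask$height - 1)) {
    warning("keep polygon extends beyond the image; vertices clipped to bounds")
    keep <- polygon_roi(cbind(pmin(pmax(x, 0), mask$width - 1),
                              pmin(pmax(y, 0), mask$height - 1)))
  }
  keep_bits <- rasterize_polygon(keep, mask$height, mask$width)
  region_mask(mask$bits & keep_bits$bits)
}

quant_result <- function(sample_id, method, explant_area, sprout_area,
                         threshold_used, overlay_path = NA_character_) {
  structure(
    list(sample_id = sample_id, method = method,
         explant_area = explant_area, sprout_area = sprout_area,
         threshold_used = threshold_used, overlay_path = overlay_path),
    class = "quant_result"
  )
}

#' @export
print.quant_result <- function(x, ...) {
  cat(sprintf("<quant_result> %s [%s]: explant %d px (%.4g mm^2), sprouts %d px (%.4g mm^2), threshold %s\n",
              x$sample_id, x$method,
              x$explant_area$pixels, x$explant_area$mm2,
              x$sprout_area$pixels, x$sprout_area$mm2,
              as.character(x$threshold_used)))
  invisible(x)
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("%s: %s", stage, conditionMessage(e)), call. = FALSE))
}

#' Computerized quantification of sprouting area
#'
#' The full computerized pipeline on one image: seeded region growing from
#' the seed point selects the explant body (wand), holes are filled, the
#' explant is deleted (and its area recorded), the remaining image is
#' thresholded to isolate the sprouts, an optional keep-polygon removes
#' background clutter, and any residual overlap with the explant mask is
#' subtracted so the sprout mask is always disjoint from the (hole-filled)
#' explant. The sprout pixel count is the assay readout; it deliberately
#' excludes the extracellular space between vessels.
#'
#' @param image an [image_grid()].
#' @param seed `c(x, y)` 0-based seed inside the explant body.
#' @param wand_tolerance wand tolerance as a fraction of dynamic range
#'   (default 0.30).
#' @param threshold_method `"otsu"` (default) or `"fixed"`.
#' @param fixed_value gray level when `threshold_method = "fixed"`.
#' @param polarity `"dark_objects"` (default) or `"bright_objects"`.
#' @param keep optional [polygon_roi()] keep-region.
#' @param sample_id label carried into the result.
#' @param overlay_path if non-NULL, a QC overlay PNG is written there.
#' @param seed_median_3x3 see [magic_wand()].
#' @param return_masks if TRUE the result carries `explant_mask` and
#'   `sprout_mask` fields (used e.g. to build the manual-method hull).
#' @return A `quant_result` with `method = "swift"`.
#' @export
swift_quantify <- function(image, seed, wand_tolerance = 0.30,
                           threshold_method = c("otsu", "fixed"),
                           fixed_value = NULL,
                           polarity = c("dark_objects", "bright_objects"),
                           keep = NULL, sample_id = NA_character_,
                           overlay_path = NULL, seed_median_3x3 = FALSE,
                           return_masks = FALSE) {
  stopifnot(inherits(image, "image_grid"))
  threshold_method <- match.arg(threshold_method)
  polarity <- match.arg(polarity)
  explant <- run_stage("magic_wand",
    magic_wand(image, seed, wand_tolerance, seed_median_3x3))
  explant <- run_stage("fill_holes", fill_holes(explant))
  deleted <- run_stage("delete_explant", delete_explant(image, explant))
  thr <- run_stage("threshold_sprouts",
    threshold_sprouts(deleted$image, threshold_method, fixed_value, polarity))
  sprouts <- run_stage("exclude_background", exclude_background(thr$mask, keep))
  # residual overlap removed last: disjointness holds whatever the threshold
  sprouts <- region_mask(sprouts$bits & !explant$bits)
  res <- quant_result(sample_id, "swift", deleted$area,
                      measure_area(sprouts, image$calibration_um_per_px),
                      thr$threshold_used)
  if (!is.null(overlay_path)) {
    run_stage("save_overlay", save_overlay(image, explant, sprouts, overlay_path))
    res$overlay_path <- overlay_path
  }
  if (return_masks) {
    res$explant_mask <- explant
    res$sprout_mask <- sprouts
  }
  res
}

#' Convex-hull outline of one or more masks
#'
#' Builds the total sprout outline used by the manual method from the union
#' of the given masks (typically explant and sprouts).
#'
#' @param ... [region_mask()]s of identical dimensions.
#' @return A [polygon_roi()].
#' @export
hull_outline <- function(...) {
  masks <- list(...)
  stopifnot(length(masks) >= 1L)
  bits <- Reduce(`|`, lapply(masks, function(m) m$bits))
  idx <- which(bits, arr.ind = TRUE)
  if (nrow(idx) < 3L) stop("too few set pixels to form a hull")
  pts <- cbind(x = idx[, "col"] - 1, y = idx[, "row"] - 1)
  h <- grDevices::chull(pts)
  polygon_roi(pts[h, , drop = FALSE])
}

#' Manual quantification of sprouting area
#'
#' The traditional method: the total area occupied by the sprouts is
#' outlined as a polygon, and the explant area is subtracted from it. The
#' outline is rasterized at pixel centers so its area is commensurable with
#' mask areas. Includes the extracellular space between vessels, so it
#' upper-bounds the computerized readout on the same sample.
#'
#' @param total_outline a [polygon_roi()] around everything the sprouts occupy.
#' @param explant a [region_mask()] or [polygon_roi()] of the explant body.
#' @param calibration_um_per_px micrometres per pixel edge.
#' @param dims `c(height, width)` canvas size; required when `explant` is a
#'   polygon, otherwise taken from the mask.
#' @param sample_id label carried into the result.
#' @return A `quant_result` with `method = "manual"` and
#'   `threshold_used = "manual-polygon"`.
#' @export
manual_quantify <- function(total_outline, explant, calibration_um_per_px,
                            dims = NULL, sample_id = NA_character_) {
  stopifnot(inherits(total_outline, "polygon_roi"))
  if (inherits(explant, "region_mask")) {
    dims <- c(explant$height, explant$width)
    explant_px <- explant$pixel_count
  } else if (inherits(explant, "polygon_roi")) {
    if (is.null(dims)) stop("dims = c(height, width) required for a polygon explant")
    explant_px <- rasterize_polygon(explant, dims[1L], dims[2L])$pixel_count
  } else {
    stop("explant must be a region_mask or polygon_roi")
  }
  total_px <- rasterize_polygon(total_outline, dims[1L], dims[2L])$pixel_count
  if (explant_px > total_px)
    stop(sprintf("explant area (%d px) exceeds the total outline (%d px); inputs swapped?",
                 explant_px, total_px))
  quant_result(sample_id, "manual",
               area_measure(explant_px, calibration_um_per_px),
               area_measure(total_px - explant_px, calibration_um_per_px),
               "manual-polygon")
}
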