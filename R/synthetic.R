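# Run expr with a fixed RNG state (Mersenne-Twister), restoring the caller's
# RNG afterwards so generation never perturbs outside randomness.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(expr)
}

# 0-based (x, y) pixels whose centers lie within radius r of the polyline
# (px, py): exact point-to-segment distances, so the painted tube's area
# per unit length does not depend on the filament's angle.
.paint_tube <- function(px, py, r, height, width) {
  m <- length(px)
  pad <- ceiling(r)
  offs <- expand.grid(dx = -pad:pad, dy = -pad:pad)
  candx <- as.vector(outer(round(px), offs$dx, `+`))
  candy <- as.vector(outer(round(py), offs$dy, `+`))
  ok <- candx >= 0 & candx < width & candy >= 0 & candy < height
  key <- candx[ok] * height + candy[ok]
  keep <- !duplicated(key)
  cx <- candx[ok][keep]; cy <- candy[ok][keep]
  ax <- px[-m]; ay <- py[-m]
  vx <- px[-1] - ax; vy <- py[-1] - ay
  L2 <- pmax(vx^2 + vy^2, 1e-12)
  dmin2 <- rep(Inf, length(cx))
  for (k in seq_len(m - 1L)) {
    t <- pmin(pmax(((cx - ax[k]) * vx[k] + (cy - ay[k]) * vy[k]) / L2[k], 0), 1)
    dx <- cx - (ax[k] + t * vx[k]); dy <- cy - (ay[k] + t * vy[k])
    dmin2 <- pmin(dmin2, dx * dx + dy * dy)
  }
  hit <- dmin2 <= r^2 + 1e-12
  cbind(x = cx[hit], y = cy[hit])
}

#' Generate one synthetic explant image with ground truth
#'
#' Emulates a phase-contrast field of a cultured explant: a dark elliptical
#' tissue body at the center of a brighter noisy background, with thin
#' darker filaments (microvascular sprouts) radiating outward. Sprouts are
#' quadratic Bezier curves with per-sprout random curvature and length
#' jitter, rasterized by stamping a disc of the requested width along the
#' curve. Ground-truth explant and sprout masks are recorded before read
#' noise is added, and the sprout truth excludes any overlap with the
#' explant body, so the two masks are always disjoint.
#'
#' Default intensities (background 220, explant 30, sprout 130 on 8 bits)
#' are chosen so the standard 30% wand window around an explant seed
#' excludes both sprouts and background, as in the real assay where the
#' wand selects only the dark compact tissue.
#'
#' @param explant_radius_px semi-major axis of the explant ellipse.
#' @param n_sprouts number of radiating filaments.
#' @param sprout_length_px nominal filament length.
#' @param length_jitter per-sprout fractional length variation (uniform in
#'   `1 ± length_jitter`); part of the biological variability, so
#'   [generate_dose_batch()] sets it to 0 for a noise-free model.
#' @param sprout_width_px filament thickness.
#' @param intensities named vector `c(background, explant, sprout)` of gray
#'   levels; sprouts must be darker than the background.
#' @param noise_sd SD of i.i.d. Gaussian read noise (gray levels), added
#'   after painting and clipped to the dynamic range.
#' @param seed RNG seed; the sample is bit-reproducible from it.
#' @param height,width canvas size in pixels.
#' @param bit_depth 8 (default) or 16.
#' @param sprout_start_px radius at which filaments are anchored; default
#'   `explant_radius_px + 2`. An explicit value decouples sprout painting
#'   from explant size.
#' @param calibration_um_per_px physical calibration carried on the image.
#' @param explant_aspect ratio of the ellipse's minor to major axis.
#' @return A `synthetic_sample`: list with `image` ([image_grid()]),
#'   `true_explant`, `true_sprouts` ([region_mask()]s), `seed_xy` (a wand
#'   seed at the explant center, 0-based), and `params_echo`.
#' @export
generate_sample <- function(explant_radius_px = 22, n_sprouts = 12,
                            sprout_length_px = 40, sprout_width_px = 3,
                            intensities = c(background = 220, explant = 30, sprout = 130),
                            noise_sd = 4, seed = 1L,
                            height = 192, width = 192, bit_depth = 8L,
                            sprout_start_px = NULL,
                            calibration_um_per_px = 1.45,
                            explant_aspect = 0.85,
                            length_jitter = 0.15) {
  maxv <- 2^bit_depth - 1
  ib <- intensities[["background"]]; ie <- intensities[["explant"]]
  is_ <- intensities[["sprout"]]
  if (any(c(ib, ie, is_) < 0) || any(c(ib, ie, is_) > maxv))
    stop("intensities out of range for bit depth")
  if (is_ >= ib)
    stop("sprout intensity must be strictly darker than the background")
  if (is.null(sprout_start_px)) sprout_start_px <- explant_radius_px + 2
  cx <- (width - 1) / 2; cy <- (height - 1) / 2
  max_reach <- sprout_start_px + sprout_length_px * (1 + length_jitter) +
    sprout_width_px
  if (explant_radius_px + sprout_width_px >= min(cx, cy) ||
      (n_sprouts > 0 && max_reach >= min(cx, cy)))
    stop(sprintf("geometry overflow: reach %.0f px exceeds the %d x %d canvas",
                 max_reach, width, height))

  params <- list(explant_radius_px = explant_radius_px, n_sprouts = n_sprouts,
                 sprout_length_px = sprout_length_px,
                 sprout_width_px = sprout_width_px,
                 intensities = intensities, noise_sd = noise_sd, seed = seed,
                 height = height, width = width, bit_depth = bit_depth,
                 sprout_start_px = sprout_start_px,
                 calibration_um_per_px = calibration_um_per_px,
                 explant_aspect = explant_aspect,
                 length_jitter = length_jitter,
                 rng = "Mersenne-Twister/Inversion")

  with_local_seed(seed, {
    # explant: rotated ellipse
    theta <- stats::runif(1, 0, pi)
    xs <- matrix(rep(0:(width - 1), each = height), height, width) - cx
    ys <- matrix(rep(0:(height - 1), width), height, width) - cy
    xr <- xs * cos(theta) + ys * sin(theta)
    yr <- -xs * sin(theta) + ys * cos(theta)
    explant_bits <- (xr / explant_radius_px)^2 +
      (yr / (explant_radius_px * explant_aspect))^2 <= 1

    # sprouts: Bezier filaments at jittered radial angles
    sprout_bits <- matrix(FALSE, height, width)
    if (n_sprouts > 0) {
      # angle jitter capped below half the spacing so neighbouring filaments
      # seldom merge at the hub (merging would couple painted area to the
      # angle draw)
      angles <- 2 * pi * (seq_len(n_sprouts) - 1) / n_sprouts +
        stats::runif(n_sprouts, -0.35 * pi / n_sprouts, 0.35 * pi / n_sprouts)
      lens <- sprout_length_px *
        stats::runif(n_sprouts, 1 - length_jitter, 1 + length_jitter)
      curvs <- stats::runif(n_sprouts, -0.2, 0.2)
      for (i in seq_len(n_sprouts)) {
        a <- angles[i]; len <- lens[i]
        p0 <- c(cx + sprout_start_px * cos(a), cy + sprout_start_px * sin(a))
        p2 <- c(p0[1] + len * cos(a), p0[2] + len * sin(a))
        mid <- (p0 + p2) / 2
        p1 <- mid + curvs[i] * len * c(-sin(a), cos(a))
        tt <- seq(0, 1, length.out = max(8L, ceiling(1.5 * len)))
        bx <- (1 - tt)^2 * p0[1] + 2 * tt * (1 - tt) * p1[1] + tt^2 * p2[1]
        by <- (1 - tt)^2 * p0[2] + 2 * tt * (1 - tt) * p1[2] + tt^2 * p2[2]
        # rescale about the anchor so the arc length (not the chord) is len:
        # keeps painted area proportional to len regardless of curvature
        arc <- sum(sqrt(diff(bx)^2 + diff(by)^2))
        bx <- p0[1] + (bx - p0[1]) * (len / arc)
        by <- p0[2] + (by - p0[2]) * (len / arc)
        xy <- .paint_tube(bx, by, sprout_width_px / 2, height, width)
        sprout_bits[cbind(xy[, "y"] + 1L, xy[, "x"] + 1L)] <- TRUE
      }
    }
    sprout_bits <- sprout_bits & !explant_bits

    img <- matrix(ib, height, width)
    img[explant_bits] <- ie
    img[sprout_bits] <- is_
    if (noise_sd > 0)
      img <- img + stats::rnorm(length(img), 0, noise_sd)
    img <- matrix(as.integer(pmin(pmax(round(img), 0), maxv)), height, width)

    structure(
      list(image = image_grid(img, as.integer(bit_depth), calibration_um_per_px),
           true_explant = region_mask(explant_bits),
           true_sprouts = region_mask(sprout_bits),
           seed_xy = c(x = round(cx), y = round(cy)),
           params_echo = params),
      class = "synthetic_sample")
  })
}

#' Saturating dose-response model for synthetic batches
#'
#' Expected true sprout area at dose `d` follows an Emax curve:
#' `area(d) = baseline * (1 + emax * d / (d + ec50))`, a bounded saturating
#' response; `emax < 0` models an anti-angiogenic compound (suppression),
#' `emax > 0` a pro-angiogenic one. Sample-to-sample biological variability
#' is a multiplicative lognormal factor with unit mean and coefficient of
#' variation `noise_cv`.
#'
#' @param baseline_area_px expected true sprout area (pixels) at dose 0.
#' @param emax fractional maximal effect, >= -1.
#' @param ec50 dose of half-maximal effect, > 0.
#' @param noise_cv coefficient of variation of the per-sample lognormal
#'   multiplier.
#' @return A `growth_model` list.
#' @export
growth_model <- function(baseline_area_px = 1100, emax = 1, ec50 = 50,
                         noise_cv = 0.15) {
  stopifnot(baseline_area_px > 0, ec50 > 0, noise_cv >= 0)
  if (emax < -1) stop("emax must be >= -1 (area cannot go negative)")
  structure(list(baseline_area_px = baseline_area_px, emax = emax,
                 ec50 = ec50, noise_cv = noise_cv),
            class = "growth_model")
}

#' Expected area under a growth model
#' @param model a [growth_model()].
#' @param dose dose vector.
#' @return Expected true sprout area in pixels at each dose.
#' @export
expected_area <- function(model, dose) {
  stopifnot(inherits(model, "growth_model"))
  a <- model$baseline_area_px * (1 + model$emax * dose / (dose + model$ec50))
  if (any(a <= 0)) stop("model yields non-positive expected area at some dose")
  a
}

#' Generate a dose-response batch of synthetic explant images
#'
#' Emulates a dose-response experiment: `n_per_dose` explants per dose, with
#' expected true sprout area following the [growth_model()] Emax curve and
#' per-sample lognormal biological noise. Dose 0 is the vehicle control and
#' is labeled group `"control"`. Per-sample target areas are realized by
#' scaling filament count and length (each roughly with the square root of
#' the area factor, lengths clamped to the canvas with count compensating),
#' so area tracks the model while the morphology stays plausible.
#'
#' @param model a [growth_model()].
#' @param doses dose levels; must include 0.
#' @param n_per_dose samples per dose (>= 2).
#' @param seed batch RNG seed; per-sample seeds are derived from it.
#' @param dir output directory for images + CSVs (created if needed);
#'   required when `write_images = TRUE`.
#' @param write_images write 8-bit TIFFs plus `manifest.csv` and `truth.csv`
#'   to `dir` (default); if FALSE everything stays in memory and
#'   `image_path` is `NA`.
#' @param batch_label batch id recorded in the manifest.
#' @param base_n_sprouts,sprout_width_px,explant_radius_px,noise_sd,height,width
#'   geometry passed to [generate_sample()].
#' @param calibration_um_per_px physical calibration recorded per sample.
#' @return List with `manifest` (data.frame), `truth` (data.frame:
#'   `sample_id, true_explant_px, true_sprout_px, dose, target_area_px`) and
#'   `samples` (named list of `synthetic_sample`s).
#' @export
generate_dose_batch <- function(model = growth_model(), doses = c(0, 10, 50, 250),
                                n_per_dose = 8, seed = 1L, dir = NULL,
                                write_images = TRUE, batch_label = "batch1",
                                base_n_sprouts = 12, sprout_width_px = 3,
                                explant_radius_px = 22, noise_sd = 4,
                                height = 192, width = 192,
                                calibration_um_per_px = 1.45) {
  stopifnot(inherits(model, "growth_model"))
  if (!any(doses == 0)) stop("doses must include 0 (the vehicle control group)")
  if (n_per_dose < 2) stop("n_per_dose must be >= 2")
  if (write_images) {
    if (is.null(dir)) stop("dir required when write_images = TRUE")
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  }
  sprout_start <- explant_radius_px + 2
  len_max <- (min(height, width) - 1) / 2 - sprout_start - sprout_width_px - 2
  len_max <- len_max / 1.15            # allow for per-sprout length jitter
  w_eff <- sprout_width_px             # ~pixels of area per unit filament length
  cap_px <- pi * (sprout_width_px / 2)^2   # round end-cap overhead per filament
  sdlog <- sqrt(log(1 + model$noise_cv^2))

  exp_area <- expected_area(model, doses)
  rows <- list(); truths <- list(); samples <- list()
  k <- 0L
  for (di in seq_along(doses)) {
    d <- doses[di]
    group <- if (d == 0) "control" else paste0("dose_", format(d, trim = TRUE))
    for (j in seq_len(n_per_dose)) {
      k <- k + 1L
      sample_seed <- (as.integer(seed) + 7919L * k) %% .Machine$integer.max
      mult <- with_local_seed(sample_seed + 1L,
        stats::rlnorm(1, meanlog = -sdlog^2 / 2, sdlog = sdlog))
      target <- exp_area[di] * mult
      f <- target / model$baseline_area_px
      n_i <- max(4L, round(base_n_sprouts * sqrt(f)))
      len_i <- (target / n_i - cap_px) / w_eff
      if (len_i > len_max) {
        n_i <- as.integer(ceiling(target / (len_max * w_eff + cap_px)))
        len_i <- (target / n_i - cap_px) / w_eff
      }
      len_i <- max(len_i, 2 * sprout_width_px)
      sid <- sprintf("%s_d%s_s%02d", batch_label, format(d, trim = TRUE), j)
      smp <- generate_sample(explant_radius_px = explant_radius_px,
                             n_sprouts = n_i, sprout_length_px = len_i,
                             sprout_width_px = sprout_width_px,
                             noise_sd = noise_sd, seed = sample_seed,
                             height = height, width = width,
                             sprout_start_px = sprout_start,
                             calibration_um_per_px = calibration_um_per_px,
                             length_jitter = if (model$noise_cv > 0) 0.15 else 0)
      path <- NA_character_
      if (write_images) {
        path <- file.path(dir, paste0(sid, ".tif"))
        save_image(smp$image, path)
      }
      rows[[k]] <- data.frame(sample_id = sid, image_path = path,
                              seed_x = smp$seed_xy[["x"]],
                              seed_y = smp$seed_xy[["y"]],
                              group = group, batch = batch_label,
                              calibration_um_per_px = calibration_um_per_px,
                              roi_path = NA_character_,
                              stringsAsFactors = FALSE)
      truths[[k]] <- data.frame(sample_id = sid,
                                true_explant_px = smp$true_explant$pixel_count,
                                true_sprout_px = smp$true_sprouts$pixel_count,
                                dose = d, target_area_px = target,
                                stringsAsFactors = FALSE)
      samples[[sid]] <- smp
    }
  }
  manifest <- do.call(rbind, rows)
  truth <- do.call(rbind, truths)
  if (write_images) {
    write_manifest(manifest, file.path(dir, "manifest.csv"))
    utils::write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE)
  }
  list(manifest = manifest, truth = truth, samples = samples)
}
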