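#' Run the full quantification pipeline over a manifest
#'
#' Batch driver: for every manifest row, load the image, quantify sprouting
#' (the computerized "swift" method and/or the manual convex-hull variant), normalize to the
#' within-batch control mean, compare groups, and write results. Outputs in
#' `output_dir`:
#' \describe{
#'   \item{`results.csv`}{one row per sample per method with columns
#'     `sample_id,batch,group,method,explant_px,explant_mm2,sprout_px,sprout_mm2,normalized_percent`.}
#'   \item{`stats_report.txt` / `stats_pairwise.csv`}{group comparison per
#'     method (t-test for 2 groups, one-way ANOVA + Bonferroni pairwise
#'     otherwise, on the normalized percentages).}
#'   \item{`run_config.json`}{all materialized settings, for provenance.}
#'   \item{`pipeline.log`}{package version, config MD5, per-sample timing.}
#'   \item{`failures.csv`}{only with `skip_errors = TRUE` and failures.}
#' }
#'
#' @param manifest path to a manifest CSV or a data.frame from
#'   [load_manifest()] / [generate_dose_batch()].
#' @param output_dir directory for outputs (created if needed).
#' @param control_label control group label (default `"control"`).
#' @param wand_tolerance,threshold_method,fixed_value,polarity,seed_median_3x3
#'   passed to [swift_quantify()].
#' @param method `"swift"` (default), `"manual"`, or `"both"`. The manual
#'   variant outlines the convex hull of the segmented explant+sprout masks.
#' @param overlay write QC overlays next to the results.
#' @param skip_errors log per-sample failures and continue instead of
#'   stopping (default FALSE).
#' @return Invisibly, a list with `results` (data.frame), `stats` (named
#'   list of `stats_report` per method, NULL with < 2 groups), `failures`
#'   (data.frame) and `output_dir`.
#' @export
run_batch <- function(manifest, output_dir,
                      control_label = "control",
                      wand_tolerance = 0.30,
                      threshold_method = c("otsu", "fixed"), fixed_value = NULL,
                      polarity = c("dark_objects", "bright_objects"),
                      method = c("swift", "manual", "both"),
                      overlay = FALSE, skip_errors = FALSE,
                      seed_median_3x3 = FALSE) {
  threshold_method <- match.arg(threshold_method)
  polarity <- match.arg(polarity)
  method <- match.arg(method)
  if (is.character(manifest)) manifest <- load_manifest(manifest)
  manifest <- as.data.frame(manifest)
  if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)

  config <- list(control_label = control_label, wand_tolerance = wand_tolerance,
                 threshold_method = threshold_method, fixed_value = fixed_value,
                 polarity = polarity, method = method, overlay = overlay,
                 skip_errors = skip_errors, seed_median_3x3 = seed_median_3x3,
                 n_samples = nrow(manifest),
                 package_version = as.character(utils::packageVersion("sproutquant")))
  config_path <- file.path(output_dir, "run_config.json")
  jsonlite::write_json(config, config_path, auto_unbox = TRUE, null = "null",
                       digits = NA)
  log_lines <- c(
    sprintf("sproutquant %s", config$package_version),
    sprintf("config md5: %s", unname(tools::md5sum(config_path))),
    sprintf("samples: %d, method: %s", nrow(manifest), method))

  do_swift <- method %in% c("swift", "both")
  do_manual <- method %in% c("manual", "both")
  rows <- list(); failures <- list()
  for (i in seq_len(nrow(manifest))) {
    m <- manifest[i, ]
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch({
      img <- run_stage("load_image",
        load_image(m$image_path, m$calibration_um_per_px))
      keep <- NULL
      if (!is.null(m$roi_path) && !is.na(m$roi_path) && nzchar(m$roi_path))
        keep <- run_stage("load_roi", load_roi(m$roi_path))
      overlay_path <- if (overlay)
        file.path(output_dir, paste0(m$sample_id, "_swift_overlay.png")) else NULL
      sq <- swift_quantify(img, c(m$seed_x, m$seed_y),
                           wand_tolerance = wand_tolerance,
                           threshold_method = threshold_method,
                           fixed_value = fixed_value, polarity = polarity,
                           keep = keep, sample_id = m$sample_id,
                           overlay_path = overlay_path,
                           seed_median_3x3 = seed_median_3x3,
                           return_masks = TRUE)
      out <- list()
      if (do_swift) out$swift <- sq
      if (do_manual) {
        hull <- run_stage("hull_outline",
          hull_outline(sq$explant_mask, sq$sprout_mask))
        out$manual <- run_stage("manual_quantify",
          manual_quantify(hull, sq$explant_mask, m$calibration_um_per_px,
                          sample_id = m$sample_id))
      }
      out
    }, error = function(e) e)
    elapsed <- proc.time()[["elapsed"]] - t0
    if (inherits(res, "error")) {
      msg <- conditionMessage(res)
      if (!skip_errors)
        stop(sprintf("sample %s: %s", m$sample_id, msg), call. = FALSE)
      failures[[length(failures) + 1L]] <-
        data.frame(sample_id = m$sample_id, error = msg, stringsAsFactors = FALSE)
      log_lines <- c(log_lines, sprintf("%s: FAILED (%s) [%.3fs]",
                                        m$sample_id, msg, elapsed))
      next
    }
    for (r in res) {
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = r$sample_id, batch = m$batch, group = m$group,
        method = r$method,
        explant_px = r$explant_area$pixels, explant_mm2 = r$explant_area$mm2,
        sprout_px = r$sprout_area$pixels, sprout_mm2 = r$sprout_area$mm2,
        stringsAsFactors = FALSE)
    }
    log_lines <- c(log_lines, sprintf("%s: ok [%.3fs]", m$sample_id, elapsed))
  }
  failures <- if (length(failures)) do.call(rbind, failures) else
    data.frame(sample_id = character(), error = character())
  if (!length(rows))
    stop("no sample was quantified successfully")
  results <- do.call(rbind, rows)
  results <- normalize_to_control(results, control_label)

  utils::write.csv(results, file.path(output_dir, "results.csv"),
                   row.names = FALSE, quote = FALSE)
  if (nrow(failures))
    utils::write.csv(failures, file.path(output_dir, "failures.csv"),
                     row.names = FALSE)

  stats_out <- list()
  pw_rows <- list()
  for (meth in unique(results$method)) {
    sub <- results[results$method == meth, ]
    if (length(unique(sub$group)) < 2L ||
        any(table(sub$group) < 2L)) { stats_out[meth] <- list(NULL); next }
    rep <- suppressMessages(
      compare_many(sub$normalized_percent, sub$group))
    stats_out[[meth]] <- rep
    pw <- rep$pairwise; pw$method <- meth
    pw_rows[[meth]] <- pw
  }
  txt <- file.path(output_dir, "stats_report.txt")
  con <- file(txt, "w")
  for (meth in names(stats_out)) {
    cat(sprintf("== method: %s ==\n", meth), file = con)
    if (is.null(stats_out[[meth]])) {
      cat("fewer than 2 groups with n >= 2; no test performed\n", file = con)
    } else {
      sink(con); print(stats_out[[meth]]); sink()
    }
  }
  close(con)
  if (length(pw_rows))
    utils::write.csv(do.call(rbind, pw_rows),
                     file.path(output_dir, "stats_pairwise.csv"),
                     row.names = FALSE)
  writeLines(log_lines, file.path(output_dir, "pipeline.log"))
  invisible(list(results = results, stats = stats_out,
                 failures = failures, output_dir = output_dir))
}
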