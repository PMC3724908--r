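#' Normalize sprouting areas to the within-batch control mean
#'
#' Absolute sprouting areas drift between independent experiments (tissue
#' preparation, culture conditions), so treatment effects are expressed as a
#' percentage of the mean control area *within the same batch*:
#' `normalized_percent = 100 * raw / mean(raw of control samples in batch)`.
#' Raw values are preserved alongside. Explant size is never used for
#' normalization — explant area is subtracted upstream, not divided out.
#'
#' When a `method` column is present (swift/manual), normalization is
#' performed within batch x method so the two readouts, which differ in
#' absolute scale, stay comparable after normalization.
#'
#' @param results data.frame with at least `sample_id`, `group`, `batch` and
#'   the value column.
#' @param control_label group label identifying control samples
#'   (default `"control"`).
#' @param value_col column holding the raw sprout area (default `"sprout_px"`).
#' @return The input data.frame with a `normalized_percent` column appended.
#' @export
normalize_to_control <- function(results, control_label = "control",
                                 value_col = "sprout_px") {
  df <- as.data.frame(results)
  need <- c("sample_id", "group", "batch", value_col)
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("results are missing column(s): %s", paste(miss, collapse = ", ")))
  key <- if ("method" %in% names(df)) {
    interaction(df$batch, df$method, drop = TRUE)
  } else {
    factor(df$batch)
  }
  df$normalized_percent <- NA_real_
  for (k in levels(key)) {
    sel <- key == k
    ctrl <- sel & df$group == control_label
    if (!any(ctrl))
      stop(sprintf("batch '%s' has no '%s' samples to normalize against",
                   unique(as.character(df$batch[sel]))[1L], control_label))
    ctrl_mean <- mean(df[[value_col]][ctrl])
    if (!is.finite(ctrl_mean) || ctrl_mean <= 0)
      stop(sprintf("control mean for batch '%s' is not positive",
                   unique(as.character(df$batch[sel]))[1L]))
    df$normalized_percent[sel] <- 100 * df[[value_col]][sel] / ctrl_mean
  }
  df
}

#' Per-group n, mean and SEM
#'
#' `sem = sd / sqrt(n)` with the sample (n - 1) standard deviation; reported
#' as `NA` for singleton groups, where it is undefined.
#'
#' @param groups either a named list of numeric vectors, or a numeric vector
#'   (with `labels` giving the group of each element).
#' @param labels group labels, used when `groups` is a plain vector.
#' @return data.frame with columns `group`, `n`, `mean`, `sem`.
#' @export
summarize_groups <- function(groups, labels = NULL) {
  gl <- if (is.list(groups)) groups else split(as.numeric(groups), labels)
  if (any(lengths(gl) == 0L)) stop("empty group")
  out <- data.frame(
    group = names(gl),
    n = lengths(gl),
    mean = vapply(gl, mean, numeric(1)),
    sem = vapply(gl, function(v)
      if (length(v) < 2L) NA_real_ else stats::sd(v) / sqrt(length(v)),
      numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  out
}

#' Two-tailed unpaired t-test between two groups
#'
#' Pooled-variance Student's t-test by default (`var_equal = TRUE`), the
#' classical form for this assay's comparisons; Welch's unequal-variance
#' test is available behind `var_equal = FALSE`. Degenerate case: when the
#' pooled variance is zero and the means are equal, `t = 0, p = 1` by
#' convention (all observations identical carry no evidence either way).
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @param var_equal pooled-variance Student test if TRUE (default).
#' @return A `stats_report` list: `test = "t_test"`, `statistic` (t), `df`,
#'   `p_value`, and `groups` (the [summarize_groups()] table).
#' @export
compare_two <- function(a, b, var_equal = TRUE) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 observations")
  groups <- summarize_groups(list(a = a, b = b))
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b)) {
      tt <- list(statistic = 0, parameter = length(a) + length(b) - 2, p.value = 1)
    } else {
      tt <- list(statistic = sign(mean(a) - mean(b)) * Inf,
                 parameter = length(a) + length(b) - 2, p.value = 0)
    }
  } else {
    ht <- stats::t.test(a, b, var.equal = var_equal)
    tt <- list(statistic = unname(ht$statistic), parameter = unname(ht$parameter),
               p.value = ht$p.value)
  }
  structure(list(test = "t_test", statistic = tt$statistic, df = tt$parameter,
                 p_value = tt$p.value, groups = groups),
            class = "stats_report")
}

#' One- or two-way ANOVA with Bonferroni-corrected pairwise t-tests
#'
#' Fixed-effects ANOVA across the group labels (one-way), or across two
#' crossed factors with interaction (two-way, Type II sums of squares — the
#' assay's designs are near-balanced, where Type II is well defined without
#' an ordering choice). Pairwise group comparisons use unpaired
#' pooled-variance t-tests with Bonferroni multiplication over the pairs
#' actually tested (`p_adj = min(1, p_raw * n_pairs)`). Normality is assumed,
#' as is standard for this assay; a caveat is emitted when any group has
#' fewer than 4 observations.
#'
#' @param values numeric vector of observations.
#' @param groups group label of each observation (primary factor).
#' @param factor2 optional second crossed factor for two-way ANOVA; pairwise
#'   comparisons remain between levels of `groups`, pooled over `factor2`.
#' @return A `stats_report` list: `test = "anova"`, `terms` (data.frame of
#'   term, df, F, p), `pairwise` (data.frame of group pair, t, df, raw and
#'   Bonferroni-adjusted p), `groups` (summary table), and for the one-way
#'   case `statistic`, `df`, `p_value` mirroring the group term.
#' @export
compare_many <- function(values, groups, factor2 = NULL) {
  values <- as.numeric(values)
  g <- factor(groups)
  if (nlevels(g) < 2L) stop("need at least 2 group levels")
  if (any(table(g) < 2L)) stop("each group needs at least 2 observations")
  if (any(table(g) < 4L))
    message("note: group n < 4; normality is assumed, not testable at this size")
  if (is.null(factor2)) {
    fit <- stats::aov(values ~ g)
    an <- stats::anova(fit)
    ssb <- an[["Sum Sq"]][1L]; sse <- an[["Sum Sq"]][2L]
    if (sse == 0) {                      # perfectly deterministic cells
      Fv <- if (ssb == 0) 0 else Inf
      pv <- if (ssb == 0) 1 else 0
    } else {
      Fv <- an[["F value"]][1L]; pv <- an[["Pr(>F)"]][1L]
    }
    terms <- data.frame(term = "group", df = an$Df[1L], df_resid = an$Df[2L],
                        F = Fv, p = pv, stringsAsFactors = FALSE)
  } else {
    f2 <- factor(factor2)
    if (nlevels(f2) < 2L) stop("factor2 needs at least 2 levels")
    cell <- table(g, f2)
    if (any(cell == 0L)) stop("empty cells: two-way ANOVA with interaction needs every group x factor2 cell filled")
    fit <- stats::aov(values ~ g * f2)
    an <- car::Anova(fit, type = 2)
    keep <- rownames(an) != "Residuals"
    terms <- data.frame(term = c("group", "factor2", "group:factor2"),
                        df = an$Df[keep], df_resid = an$Df[!keep],
                        F = an$`F value`[keep], p = an$`Pr(>F)`[keep],
                        stringsAsFactors = FALSE)
  }
  lv <- levels(g)
  pairs <- utils::combn(lv, 2L)
  pw <- data.frame(group1 = pairs[1L, ], group2 = pairs[2L, ],
                   t = NA_real_, df = NA_real_, p_raw = NA_real_,
                   stringsAsFactors = FALSE)
  for (i in seq_len(ncol(pairs))) {
    ct <- compare_two(values[g == pairs[1L, i]], values[g == pairs[2L, i]])
    pw$t[i] <- ct$statistic; pw$df[i] <- ct$df; pw$p_raw[i] <- ct$p_value
  }
  pw$p_adj <- stats::p.adjust(pw$p_raw, method = "bonferroni")
  out <- list(test = "anova", terms = terms, pairwise = pw,
              groups = summarize_groups(split(values, g)),
              statistic = terms$F[1L], df = terms$df[1L], p_value = terms$p[1L])
  structure(out, class = "stats_report")
}

#' @export
print.stats_report <- function(x, ...) {
  if (x$test == "t_test") {
    cat(sprintf("Unpaired two-tailed t-test: t = %.4f, df = %g, p = %.4g\n",
                x$statistic, x$df, x$p_value))
  } else {
    cat("ANOVA:\n")
    for (i in seq_len(nrow(x$terms)))
      cat(sprintf("  %s: F(%g, %g) = %.4f, p = %.4g\n", x$terms$term[i],
                  x$terms$df[i], x$terms$df_resid[i], x$terms$F[i], x$terms$p[i]))
    cat("Pairwise (Bonferroni-adjusted):\n")
    for (i in seq_len(nrow(x$pairwise)))
      cat(sprintf("  %s vs %s: t = %.4f, p_adj = %.4g\n",
                  x$pairwise$group1[i], x$pairwise$group2[i],
                  x$pairwise$t[i], x$pairwise$p_adj[i]))
  }
  cat("Group means +/- SEM:\n")
  for (i in seq_len(nrow(x$groups)))
    cat(sprintf("  %s: %.4g +/- %.4g (n = %d)\n", x$groups$group[i],
                x$groups$mean[i], x$groups$sem[i], x$groups$n[i]))
  invisible(x)
}
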