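make_results <- function(values, groups, batch = "b1", method = NULL) {
  df <- data.frame(sample_id = paste0("s", seq_along(values)),
                   group = groups, batch = batch, sprout_px = values,
                   stringsAsFactors = FALSE)
  if (!is.null(method)) df$method <- method
  df
}

test_that("normalization to control gives mean 100 controls and ratio-scaled treated", {
  df <- make_results(c(2, 4, 6), c("control", "control", "treated"))
  nz <- normalize_to_control(df)
  expect_equal(nz$normalized_percent, c(200 / 3, 400 / 3, 200))
  expect_equal(mean(nz$normalized_percent[nz$group == "control"]), 100)

  # all samples equal -> all 100
  eq <- normalize_to_control(make_results(rep(7, 5),
                                          c("control", "control", "t", "t", "t")))
  expect_equal(eq$normalized_percent, rep(100, 5))

  # two batches, different absolute scales, same treated/control ratio
  b1 <- make_results(c(10, 20, 45), c("control", "control", "t"), "b1")
  b2 <- make_results(c(100, 200, 450), c("control", "control", "t"), "b2")
  nz2 <- normalize_to_control(rbind(b1, b2))
  expect_equal(nz2$normalized_percent[nz2$batch == "b1"],
               nz2$normalized_percent[nz2$batch == "b2"])

  expect_error(normalize_to_control(make_results(c(1, 2), c("t", "t"))),
               "no 'control'")
  expect_error(normalize_to_control(make_results(c(0, 0, 1),
                                                 c("control", "control", "t"))),
               "not positive")
})

test_that("normalization is idempotent and permutation-safe", {
  set.seed(99)
  df <- make_results(rgamma(12, 5, 1 / 50),
                     rep(c("control", "a", "b"), 4),
                     rep(c("b1", "b2"), each = 6))
  nz1 <- normalize_to_control(df)
  renz <- normalize_to_control(
    transform(nz1, sprout_px = normalized_percent))
  expect_equal(renz$normalized_percent, nz1$normalized_percent)

  perm <- sample(nrow(df))
  nz_p <- normalize_to_control(df[perm, ])
  expect_equal(nz_p$normalized_percent[order(nz_p$sample_id)],
               nz1$normalized_percent[order(nz1$sample_id)])
})

test_that("summaries report n, mean and the (n-1)/sqrt(n) SEM", {
  s <- summarize_groups(list(g = c(1, 2, 3)))
  expect_equal(s$mean, 2)
  expect_equal(s$sem, 1 / sqrt(3))

  s1 <- summarize_groups(list(g = 5))
  expect_equal(s1$mean, 5)
  expect_true(is.na(s1$sem))

  expect_equal(summarize_groups(list(g = c(4, 4, 4)))$sem, 0)
  expect_error(summarize_groups(list(g = numeric(0))), "empty")

  # vector + labels interface
  sv <- summarize_groups(c(1, 2, 3, 10, 20), c("a", "a", "a", "b", "b"))
  expect_equal(sv$n, c(3L, 2L))
})

test_that("pooled t-test matches the closed form and its invariances", {
  r <- compare_two(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$statistic, -3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(r$df, 4)
  expect_equal(r$p_value, 2 * pt(-3 / sqrt(2 / 3), 4), tolerance = 1e-12)

  same <- compare_two(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  # zero variance, equal means: p = 1 by convention
  flat <- compare_two(c(2, 2), c(2, 2))
  expect_equal(flat$p_value, 1)

  # positive scaling leaves t and p unchanged
  a <- c(1.2, 3.4, 2.2, 5.1); b <- c(4.4, 6.1, 5.0)
  r1 <- compare_two(a, b); r2 <- compare_two(10 * a, 10 * b)
  expect_equal(r1$statistic, r2$statistic)
  expect_equal(r1$p_value, r2$p_value)

  expect_error(compare_two(1, c(1, 2)), "at least 2")
})

test_that("one-way ANOVA matches hand-computed sums of squares and F = t^2", {
  # three groups, n = 3, integer-friendly values
  vals <- c(1, 2, 3, 4, 5, 6, 8, 9, 10)
  grp <- rep(c("a", "b", "c"), each = 3)
  # brute-force sums of squares
  gm <- mean(vals)
  means <- tapply(vals, grp, mean)
  ssb <- sum(3 * (means - gm)^2)
  ssw <- sum((vals - means[grp])^2)
  f_oracle <- (ssb / 2) / (ssw / 6)
  r <- suppressMessages(compare_many(vals, grp))
  expect_equal(r$statistic, f_oracle, tolerance = 1e-12)
  expect_equal(r$p_value, pf(f_oracle, 2, 6, lower.tail = FALSE), tolerance = 1e-12)

  # identical groups: F = 0, p = 1
  z <- suppressMessages(compare_many(rep(c(1, 2, 3), 3), rep(c("a", "b", "c"), each = 3)))
  expect_equal(z$statistic, 0)
  expect_equal(z$p_value, 1)

  # two-group one-way F equals t^2 from the pooled t-test
  a <- c(3.1, 4.5, 2.2, 5.0); b <- c(6.3, 7.7, 5.9)
  tt <- compare_two(a, b)
  av <- suppressMessages(compare_many(c(a, b), rep(c("a", "b"), c(4, 3))))
  expect_equal(av$statistic, tt$statistic^2, tolerance = 1e-9)
  expect_equal(av$p_value, tt$p_value, tolerance = 1e-9)
})

test_that("Bonferroni multiplies by the number of pairs and caps at 1", {
  expect_equal(p.adjust(0.01, "bonferroni", n = 3), 0.03)
  set.seed(123)
  vals <- c(rnorm(4, 0), rnorm(4, 0.2), rnorm(4, 5))
  r <- compare_many(vals, rep(c("a", "b", "c"), each = 4))
  expect_equal(nrow(r$pairwise), 3)
  expect_true(all(r$pairwise$p_adj >= r$pairwise$p_raw))
  expect_true(all(r$pairwise$p_adj <= 1 & r$pairwise$p_adj >= 0))
  expect_equal(r$pairwise$p_adj,
               pmin(1, r$pairwise$p_raw * 3))
})

test_that("two-way ANOVA reports both factors and the interaction", {
  set.seed(7)
  g <- rep(rep(c("control", "treated"), each = 4), 2)
  meth <- rep(c("swift", "manual"), each = 8)
  y <- rnorm(16) + ifelse(g == "treated", 2, 0)
  r <- compare_many(y, g, factor2 = meth)
  expect_equal(r$terms$term, c("group", "factor2", "group:factor2"))
  expect_true(r$terms$p[1] < 0.05)   # group effect detected
  expect_true(all(r$terms$p >= 0 & r$terms$p <= 1))

  # empty cell rejected
  expect_error(compare_many(y[meth == "swift" | g == "control"],
                            g[meth == "swift" | g == "control"],
                            factor2 = meth[meth == "swift" | g == "control"]),
               "empty cells")
})
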