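#' Normality-gated two-sample test selection
#'
#' Reproduces the study's test-selection logic: Shapiro-Wilk normality on
#' each sample (non-normal at `alpha_normality` in either sample selects the
#' Mann-Whitney U test); for normal samples, variance homogeneity is checked
#' with a Brown-Forsythe (median-centred Levene) test, falling back to the
#' nonparametric test (or Welch's t, by choice) when variances differ;
#' otherwise the unpaired two-tailed Student t-test is used.
#'
#' Shapiro-Wilk is undefined above n = 5000; larger samples are gated on a
#' deterministic evenly-spaced subsample of 5000 values.
#'
#' @param x,y numeric samples, each n >= 3.
#' @param alpha_normality normality gate level (default 0.05).
#' @param unequal_var_fallback `"mann_whitney_u"` (default) or `"welch_t"`.
#' @return `"mann_whitney_u"`, `"t_test"` or `"welch_t"`.
#' @export
choose_test <- function(x, y, alpha_normality = 0.05,
                        unequal_var_fallback = c("mann_whitney_u", "welch_t")) {
  unequal_var_fallback <- match.arg(unequal_var_fallback)
  if (length(x) < 3 || length(y) < 3)
    stop("each sample needs n >= 3 (Shapiro-Wilk is undefined below that)")
  sw <- function(v) {
    if (length(v) > 5000)
      v <- v[round(seq(1, length(v), length.out = 5000))]
    if (stats::sd(v) == 0) return(0) # degenerate: treat as non-normal
    stats::shapiro.test(v)$p.value
  }
  if (sw(x) < alpha_normality || sw(y) < alpha_normality)
    return("mann_whitney_u")
  if (levene_test(x, y)$p.value < 0.05) return(unequal_var_fallback)
  "t_test"
}

#' Brown-Forsythe (median-centred Levene) test for two samples
#'
#' One-way ANOVA on absolute deviations from the group medians, the robust
#' variant of Levene's variance-homogeneity test.
#'
#' @param x,y numeric samples.
#' @return list with `statistic` (F), `p.value`, `df`.
#' @export
levene_test <- function(x, y) {
  zx <- abs(x - stats::median(x))
  zy <- abs(y - stats::median(y))
  z <- c(zx, zy)
  g <- rep(1:2, c(length(zx), length(zy)))
  n <- length(z); k <- 2
  zbar <- mean(z)
  mg <- tapply(z, g, mean)
  ng <- tabulate(g)
  ssb <- sum(ng * (mg - zbar)^2)
  ssw <- sum((z - mg[g])^2)
  df1 <- k - 1; df2 <- n - k
  f <- (ssb / df1) / (ssw / df2)
  if (!is.finite(f)) f <- 0
  list(statistic = f, p.value = stats::pf(f, df1, df2, lower.tail = FALSE),
       df = c(df1, df2))
}

#' Significance label from an adjusted p-value
#'
#' The printed convention: `ns: p > 0.05; *: p <= 0.05; **: p <= 0.01;
#' ***: p <= 0.001; ****: p <= 0.0001` (boundaries inclusive).
#'
#' @param p_adjusted p-value in `[0, 1]`.
#' @return one of `"ns"`, `"*"`, `"**"`, `"***"`, `"****"`.
#' @export
significance_label <- function(p_adjusted) {
  if (!is.finite(p_adjusted) || p_adjusted < 0 || p_adjusted > 1)
    stop("p-value must lie in [0, 1]")
  if (p_adjusted <= 1e-4) "****"
  else if (p_adjusted <= 1e-3) "***"
  else if (p_adjusted <= 1e-2) "**"
  else if (p_adjusted <= 0.05) "*"
  else "ns"
}

#' Two-sample comparison with Bonferroni correction
#'
#' Runs the gate-selected (or forced) two-sided test, multiplies the raw p
#' by the family size `m` (capped at 1), and labels significance by the
#' printed convention. The Mann-Whitney p-value is exact when
#' `min(n1, n2) <= 8` and there are no ties, otherwise the normal
#' approximation with tie and continuity correction is used. `x` is the
#' control/reference group for the percent-change sign.
#'
#' @param x,y numeric samples (x = control).
#' @param m Bonferroni family size (>= 1).
#' @param test `"auto"` (gate) or one of `"mann_whitney_u"`, `"t_test"`,
#'   `"welch_t"`.
#' @param alpha_normality passed to [choose_test()].
#' @param metric optional metric name carried into the result.
#' @return a `comparison_result` list: metric, test_used, statistic, p_raw,
#'   p_adjusted, m, label, percent_change, n.
#' @export
compare_groups <- function(x, y, m = 1, test = "auto",
                           alpha_normality = 0.05, metric = NA_character_) {
  if (m < 1) stop("family size m must be >= 1")
  if (test == "auto") test <- choose_test(x, y, alpha_normality)
  if (test == "mann_whitney_u") {
    exact <- min(length(x), length(y)) <= 8 && !any(duplicated(c(x, y)))
    ht <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                              correct = TRUE,
                                              alternative = "two.sided"))
    stat <- unname(ht$statistic)
  } else if (test == "t_test") {
    ht <- stats::t.test(x, y, var.equal = TRUE, alternative = "two.sided")
    stat <- unname(ht$statistic)
  } else if (test == "welch_t") {
    ht <- stats::t.test(x, y, var.equal = FALSE, alternative = "two.sided")
    stat <- unname(ht$statistic)
  } else stop("unknown test '", test, "'")
  p_raw <- ht$p.value
  p_adj <- min(1, p_raw * m)
  structure(list(metric = metric, groups = c("x", "y"),
                 n = c(length(x), length(y)), test_used = test,
                 statistic = stat, p_raw = p_raw, p_adjusted = p_adj,
                 m = as.integer(m), label = significance_label(p_adj),
                 percent_change = percent_change(x, y)),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("%s: %s, stat = %.4g, p = %.3g (adj %.3g, m = %d) %s; %+.2f%%\n",
              ifelse(is.na(x$metric), "comparison", x$metric), x$test_used,
              x$statistic, x$p_raw, x$p_adjusted, x$m, x$label,
              x$percent_change))
  invisible(x)
}

#' Box-plot summary with 1.5 IQR outlier rule
#'
#' Five-number summary per group (quartiles by linear interpolation,
#' `stats::quantile` type 7), whisker bounds at the most extreme values
#' within 1.5 IQR of the quartiles, and the flagged outliers beyond them.
#'
#' @param samples named list of non-empty numeric vectors.
#' @return data.frame with one row per group plus an `outliers` list-column.
#' @export
boxplot_summary <- function(samples) {
  if (!is.list(samples)) samples <- list(sample = samples)
  if (any(vapply(samples, length, integer(1)) == 0))
    stop("empty group in boxplot_summary")
  rows <- lapply(seq_along(samples), function(i) {
    v <- samples[[i]]
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    iqr <- q[3] - q[1]
    lo <- q[1] - 1.5 * iqr; hi <- q[3] + 1.5 * iqr
    inside <- v[v >= lo & v <= hi]
    gname <- if (is.null(names(samples)) || names(samples)[i] == "")
      as.character(i) else names(samples)[i]
    out <- data.frame(group = gname,
                      min = min(v), q1 = q[1], median = q[2], q3 = q[3],
                      max = max(v),
                      whisker_low = min(inside), whisker_high = max(inside))
    out$outliers <- list(sort(v[v < lo | v > hi]))
    out
  })
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
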