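# Agreement and dispersion statistics, each implemented from its defining
# formula. Degenerate inputs never return NaN: they return the documented
# value with attribute "degenerate" set to TRUE, and the pipeline counts
# degenerate statistics as failing every cutoff.

flag_degenerate <- function(x, flag) {
  attr(x, "degenerate") <- flag
  x
}

#' Is a statistic flagged degenerate?
#' @param x value returned by one of the agreement statistics
#' @export
is_degenerate <- function(x) isTRUE(attr(x, "degenerate"))

#' Bland-Altman test-retest analysis
#'
#' Differences are `rescan - scan`. The limits of agreement are
#' `bias +/- 1.96 * SD` of the differences (sample SD, n-1; classical 1.96
#' multiplier, not a t quantile). `frac_within` is the fraction of paired
#' differences inside the limits; with zero SD the limits collapse onto the
#' bias and all differences are (by construction) within them. `p_bias` is a
#' two-sided one-sample t test of the differences against zero.
#'
#' @param scan,rescan paired measurement vectors (same length, n >= 3)
#' @param repeatable_cutoff fraction of pairs required within the limits
#' @return object of class `bland_altman`: list with `bias`, `sd_diff`,
#'   `loa_low`, `loa_high`, `frac_within`, `repeatable`, `p_bias`, `n`
#' @export
bland_altman <- function(scan, rescan, repeatable_cutoff = 0.90) {
  n <- length(scan)
  if (length(rescan) != n)
    stop_radrobust("scan and rescan must have equal length")
  if (n < 3L) stop_radrobust("need at least 3 pairs")
  d <- rescan - scan
  bias <- mean(d)
  sd_diff <- stats::sd(d)
  loa_low <- bias - 1.96 * sd_diff
  loa_high <- bias + 1.96 * sd_diff
  if (sd_diff == 0) {
    frac <- 1
    p <- if (bias == 0) 1 else 0
  } else {
    frac <- mean(d >= loa_low & d <= loa_high)
    tstat <- bias / (sd_diff / sqrt(n))
    p <- 2 * stats::pt(-abs(tstat), df = n - 1)
  }
  structure(
    list(bias = bias, sd_diff = sd_diff, loa_low = loa_low,
         loa_high = loa_high, frac_within = frac,
         repeatable = frac >= repeatable_cutoff, p_bias = p, n = n),
    class = "bland_altman"
  )
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf(
    "Bland-Altman (n=%d): bias %.4g, LoA [%.4g, %.4g], %.1f%% within, %s\n",
    x$n, x$bias, x$loa_low, x$loa_high, 100 * x$frac_within,
    if (x$repeatable) "repeatable" else "not repeatable"))
  invisible(x)
}

#' Coefficient of variation (percent)
#'
#' `100 * SD / |mean|` with the sample SD (n-1). The absolute mean keeps
#' negative-valued features (skewness-like) from producing negative CV. A
#' near-zero mean relative to the SD makes the ratio meaningless: the value
#' is returned as `Inf` and flagged degenerate, so it is classified
#' non-reproducible rather than dropped.
#'
#' @param values numeric vector, n >= 2
#' @export
cv_pct <- function(values) {
  if (length(values) < 2L) stop_radrobust("cv_pct needs n >= 2")
  s <- stats::sd(values)
  if (s == 0) return(flag_degenerate(0, FALSE))
  m <- abs(mean(values))
  if (m < 1e-12 * s) return(flag_degenerate(Inf, TRUE))
  flag_degenerate(100 * s / m, FALSE)
}

#' Quartile coefficient of dispersion (percent)
#'
#' `100 * (Q3 - Q1) / (Q3 + Q1)` with quartiles by linear interpolation of
#' order statistics (position `p * (n - 1) + 1`). A near-zero `Q3 + Q1`
#' yields `Inf` with the degenerate flag.
#'
#' @param values numeric vector, n >= 4
#' @export
qcd_pct <- function(values) {
  if (length(values) < 4L) stop_radrobust("qcd_pct needs n >= 4")
  q <- stats::quantile(values, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  if (iqr == 0) return(flag_degenerate(0, FALSE))
  tot <- q[1] + q[2]
  if (abs(tot) < 1e-12 * iqr) return(flag_degenerate(Inf, TRUE))
  flag_degenerate(100 * iqr / abs(tot), FALSE)
}

#' Intraclass correlation ICC(A,1)
#'
#' Single-rater, absolute-agreement, two-way random-effects ICC from the
#' two-way ANOVA mean squares: with subjects as rows and raters as columns,
#' `ICC = (MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))`.
#' Zero total variance (all cells identical) returns 1 with the degenerate
#' flag.
#'
#' @param data complete numeric matrix, n subjects x k raters (n >= 3,
#'   k >= 2)
#' @export
icc_a1 <- function(data) {
  data <- as.matrix(data)
  n <- nrow(data); k <- ncol(data)
  if (n < 3L || k < 2L) stop_radrobust("icc_a1 needs n >= 3 subjects, k >= 2 raters")
  if (anyNA(data)) stop_radrobust("icc_a1 requires a complete matrix (no imputation)")
  grand <- mean(data)
  sst <- sum((data - grand)^2)
  if (sst <= 1e-24 * max(1, grand^2))
    return(flag_degenerate(1, TRUE))
  ssr <- k * sum((rowMeans(data) - grand)^2)
  ssc <- n * sum((colMeans(data) - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  flag_degenerate(
    (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse)),
    FALSE)
}

#' Lin's concordance correlation coefficient
#'
#' `2 s_xy / (s_x^2 + s_y^2 + (mean(x) - mean(y))^2)` with population (1/n)
#' moments. Two constant vectors with equal means return 1 with the
#' degenerate flag.
#'
#' @param x,y paired numeric vectors (equal length, n >= 3)
#' @export
ccc <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop_radrobust("x and y must have equal length")
  if (n < 3L) stop_radrobust("ccc needs n >= 3")
  mx <- mean(x); my <- mean(y)
  sx2 <- mean((x - mx)^2)
  sy2 <- mean((y - my)^2)
  sxy <- mean((x - mx) * (y - my))
  den <- sx2 + sy2 + (mx - my)^2
  if (den <= 1e-24 * max(1, mx^2))
    return(flag_degenerate(1, TRUE))
  flag_degenerate(2 * sxy / den, FALSE)
}

#' Spearman rank correlation with t-approximation p value
#'
#' Ranks (average ranks for ties) are correlated with Pearson's formula;
#' the p value uses the t approximation with n - 2 degrees of freedom. The
#' squared coefficient is returned alongside, as robustness studies
#' commonly report r-squared.
#'
#' @param x,y paired numeric vectors (equal length, n >= 4)
#' @return list with `rho`, `rho_squared`, `p`, `n`
#' @export
spearman_cor <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop_radrobust("x and y must have equal length")
  if (n < 4L) stop_radrobust("spearman_cor needs n >= 4")
  if (length(unique(x)) < 2L || length(unique(y)) < 2L)
    stop_radrobust("correlation undefined for a constant vector",
                   class = "radrobust_degenerate_stat")
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  p <- if (abs(rho) >= 1) 0 else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, rho_squared = rho^2, p = p, n = n)
}
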