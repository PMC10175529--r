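#' First-order (intensity histogram) features
#'
#' Computes the 19-feature first-order set on the raw ROI values; Entropy
#' and Uniformity are computed on the discretized gray levels. Variance,
#' standard deviation and the higher moments use population (1/N)
#' normalization; Kurtosis is non-excess (a Gaussian gives 3). Total Energy
#' scales Energy by the voxel volume (in-plane spacing squared times slice
#' thickness). Percentiles use linear interpolation of order statistics.
#'
#' Degenerate contract: a constant ROI has zero variance; its Skewness and
#' Kurtosis are mapped to 0, Entropy to 0 and Uniformity to 1, so no NaN
#' escapes into the feature table.
#'
#' @param raw_values numeric vector of in-ROI HU values
#' @param discretized a `discretized_roi` of the same ROI (used for Entropy
#'   and Uniformity); computed with a default 25 HU bin width if omitted
#' @param voxel_volume_mm3 voxel volume for Total Energy
#' @return named numeric vector of length 19
#' @export
first_order_features <- function(raw_values, discretized = NULL,
                                 voxel_volume_mm3 = (500 / 512)^2 * 5) {
  x <- raw_values[!is.na(raw_values)]
  n <- length(x)
  if (n < 1L) stop_radrobust("empty ROI")
  if (is.null(discretized)) discretized <- discretize(x)
  lev <- discretized$levels[!is.na(discretized$levels)]
  p <- tabulate(lev, nbins = discretized$n_levels) / length(lev)
  p <- p[p > 0]
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  qs <- stats::quantile(x, c(0.10, 0.25, 0.50, 0.75, 0.90),
                        names = FALSE, type = 7)
  inner <- x[x >= qs[1] & x <= qs[5]]
  rmad <- if (length(inner)) mean(abs(inner - mean(inner))) else 0
  eps <- 1e-12 * max(1, mu^2)
  skew <- if (m2 <= eps) 0 else mean((x - mu)^3) / m2^1.5
  kurt <- if (m2 <= eps) 0 else mean((x - mu)^4) / m2^2
  energy <- sum(x^2)
  c(
    Energy = energy,
    TotalEnergy = voxel_volume_mm3 * energy,
    Entropy = -sum(p * log2(p)),
    Minimum = min(x),
    `10Percentile` = qs[1],
    `90Percentile` = qs[5],
    Maximum = max(x),
    Mean = mu,
    Median = qs[3],
    InterquartileRange = qs[4] - qs[2],
    Range = max(x) - min(x),
    MeanAbsoluteDeviation = mean(abs(x - mu)),
    RobustMeanAbsoluteDeviation = rmad,
    RootMeanSquared = sqrt(mean(x^2)),
    StandardDeviation = sqrt(m2),
    Skewness = skew,
    Kurtosis = kurt,
    Variance = m2,
    Uniformity = sum(p^2)
  )
}
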