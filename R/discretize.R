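#' Fixed-bin-width gray-level discretization
#'
#' Maps HU values to integer gray levels with `level(x) = floor((x - min) /
#' bin_width) + 1`, so the number of levels is `Ng = floor((max - min) /
#' bin_width) + 1`. The default bin width of 25 HU is the common convention
#' for CT radiomics with no prior intensity normalization.
#'
#' @param x numeric vector or matrix of in-ROI values; `NA` marks pixels
#'   outside the ROI (preserved in the output)
#' @param bin_width bin width in HU (> 0)
#' @return object of class `discretized_roi`: `levels` (same shape as `x`),
#'   `n_levels`, `bin_width`, `min_value`
#' @export
discretize <- function(x, bin_width = 25) {
  if (!is.numeric(bin_width) || length(bin_width) != 1L || bin_width <= 0)
    stop_radrobust("bin_width must be a positive scalar")
  vals <- x[!is.na(x)]
  if (length(vals) < 1L) stop_radrobust("no in-ROI pixels to discretize")
  mn <- min(vals)
  lev <- floor((x - mn) / bin_width) + 1
  ng <- as.integer(floor((max(vals) - mn) / bin_width) + 1)
  structure(
    list(levels = lev, n_levels = ng, bin_width = bin_width, min_value = mn),
    class = "discretized_roi"
  )
}

#' @export
print.discretized_roi <- function(x, ...) {
  cat(sprintf("DiscretizedROI: Ng = %d levels, bin width %.3g HU, min %.3g HU\n",
              x$n_levels, x$bin_width, x$min_value))
  invisible(x)
}
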