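# Gray-level dependence matrix (GLDM) features.
#
# For each in-ROI pixel, the dependence is the number of in-ROI
# 8-neighbours whose gray-level difference from the centre is <= alpha.
# The matrix is indexed by (gray level, dependence + 1): the "+1" counts
# the centre pixel itself, the usual dependence-size convention, which also
# keeps small-dependence emphases finite.

# Count of dependent neighbours for every in-ROI pixel (matrix, NA outside).
gldm_dependence_counts <- function(levels, alpha = 0, distance = 1L) {
  nr <- nrow(levels); nc <- ncol(levels)
  dep <- matrix(0, nr, nc)
  offs <- expand.grid(dr = -distance:distance, dc = -distance:distance)
  offs <- offs[!(offs$dr == 0 & offs$dc == 0), ]
  for (k in seq_len(nrow(offs))) {
    dr <- offs$dr[k]; dc <- offs$dc[k]
    sh <- matrix(NA_real_, nr, nc)
    rs <- max(1L, 1L - dr):min(nr, nr - dr)
    cs <- max(1L, 1L - dc):min(nc, nc - dc)
    sh[rs, cs] <- levels[rs + dr, cs + dc]
    dep <- dep + ifelse(!is.na(levels) & !is.na(sh) &
                          abs(levels - sh) <= alpha, 1, 0)
  }
  dep[is.na(levels)] <- NA
  dep
}

# Unnormalized dependence count matrix [level x dependence size].
gldm_matrix <- function(levels, n_levels, alpha = 0, distance = 1L) {
  dep <- gldm_dependence_counts(levels, alpha, distance)
  ok <- !is.na(levels)
  dsize <- dep[ok] + 1   # dependence size includes the centre pixel
  dmax <- max(dsize)
  counts <- tabulate((levels[ok] - 1L) * dmax + dsize,
                     nbins = n_levels * dmax)
  matrix(counts, n_levels, dmax, byrow = TRUE)
}

#' Gray-level dependence matrix features
#'
#' Dependence counts use the 8-neighbourhood (Chebyshev distance
#' `distance`) with gray-level tolerance `alpha`; only in-ROI neighbours are
#' considered at ROI edges.
#' @inheritParams glcm_features
#' @param alpha gray-level difference tolerance
#' @return named numeric vector of length 14
#' @export
gldm_features <- function(discretized, alpha = 0, distance = 1L) {
  L <- discretized$levels
  np <- sum(!is.na(L))
  P <- gldm_matrix(L, discretized$n_levels, alpha, distance)
  f <- rlm_style_features(P, np)
  c(
    DependenceEntropy = f$entropy,
    DependenceNonUniformity = f$ln,
    DependenceNonUniformityNormalized = f$lnn,
    DependenceVariance = f$lv,
    GrayLevelNonUniformity = f$gln,
    GrayLevelVariance = f$glv,
    HighGrayLevelEmphasis = f$hgl,
    LargeDependenceEmphasis = f$large,
    LargeDependenceHighGrayLevelEmphasis = f$large_hgl,
    LargeDependenceLowGrayLevelEmphasis = f$large_lgl,
    LowGrayLevelEmphasis = f$lgl,
    SmallDependenceEmphasis = f$small,
    SmallDependenceHighGrayLevelEmphasis = f$small_hgl,
    SmallDependenceLowGrayLevelEmphasis = f$small_lgl
  )
}
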