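# Gray-level co-occurrence matrix (GLCM) features.
#
# 2D extraction over the four in-plane directions at the given distance;
# matrices are symmetric and unweighted; the 24 features are computed per
# direction and then averaged (feature-then-average convention).

glcm_offsets <- function(distance = 1L) {
  list(c(0L, distance), c(distance, distance),
       c(distance, 0L), c(distance, -distance))
}

# Symmetric, unnormalized co-occurrence count matrix for one offset.
glcm_matrix <- function(levels, n_levels, offset) {
  nr <- nrow(levels); nc <- ncol(levels)
  dr <- offset[1]; dc <- offset[2]
  rs <- max(1L, 1L - dr):min(nr, nr - dr)
  cs <- max(1L, 1L - dc):min(nc, nc - dc)
  if (!length(rs) || !length(cs))
    return(matrix(0, n_levels, n_levels))
  i <- levels[rs, cs, drop = FALSE]
  j <- levels[rs + dr, cs + dc, drop = FALSE]
  ok <- !is.na(i) & !is.na(j)
  cnt <- tabulate((i[ok] - 1L) * n_levels + j[ok], nbins = n_levels^2)
  m <- matrix(cnt, n_levels, n_levels, byrow = TRUE)
  m + t(m)
}

glcm_features_single <- function(P, n_levels) {
  ng <- n_levels
  iv <- seq_len(ng)
  I <- matrix(iv, ng, ng)            # row level
  J <- t(I)                          # column level
  px <- rowSums(P); py <- colSums(P) # equal for symmetric P
  mux <- sum(iv * px); muy <- sum(iv * py)
  sx <- sqrt(sum((iv - mux)^2 * px)); sy <- sqrt(sum((iv - muy)^2 * py))
  # diagonal / cross-diagonal marginals
  k_sum <- 2:(2 * ng)
  pxy_sum <- vapply(k_sum, function(k) sum(P[I + J == k]), numeric(1))
  k_diff <- 0:(ng - 1)
  pxy_diff <- vapply(k_diff, function(k) sum(P[abs(I - J) == k]), numeric(1))
  ent <- function(q) { q <- q[q > 0]; -sum(q * log2(q)) }
  HXY <- ent(P); HX <- ent(px); HY <- ent(py)
  pp <- outer(px, py)
  nz <- P > 0 & pp > 0
  HXY1 <- -sum(P[nz] * log2(pp[nz]))
  HXY2 <- ent(pp)
  imc1 <- if (max(HX, HY) > 0) (HXY - HXY1) / max(HX, HY) else 0
  imc2 <- if (HXY2 >= HXY) sqrt(1 - exp(-2 * (HXY2 - HXY))) else 0
  corr <- if (sx > 0 && sy > 0)
    (sum(I * J * P) - mux * muy) / (sx * sy) else 1
  da <- sum(k_diff * pxy_diff)
  mcc <- glcm_mcc(P, px, py)
  off <- I != J
  c(
    Autocorrelation = sum(I * J * P),
    ClusterProminence = sum((I + J - mux - muy)^4 * P),
    ClusterShade = sum((I + J - mux - muy)^3 * P),
    ClusterTendency = sum((I + J - mux - muy)^2 * P),
    Contrast = sum((I - J)^2 * P),
    Correlation = corr,
    DifferenceAverage = da,
    DifferenceEntropy = ent(pxy_diff),
    DifferenceVariance = sum((k_diff - da)^2 * pxy_diff),
    Id = sum(P / (1 + abs(I - J))),
    Idm = sum(P / (1 + (I - J)^2)),
    Idmn = sum(P / (1 + ((I - J) / ng)^2)),
    Idn = sum(P / (1 + abs(I - J) / ng)),
    Imc1 = imc1,
    Imc2 = imc2,
    InverseVariance = if (any(off)) sum(P[off] / (I[off] - J[off])^2) else 0,
    JointAverage = mux,
    JointEnergy = sum(P^2),
    JointEntropy = HXY,
    MCC = mcc,
    MaximumProbability = max(P),
    SumAverage = sum(k_sum * pxy_sum),
    SumEntropy = ent(pxy_sum),
    SumSquares = sum((I - mux)^2 * P)
  )
}

# Maximal correlation coefficient: sqrt of the second-largest eigenvalue of
# Q[i,j] = sum_k P[i,k] P[j,k] / (px[i] py[k]), over levels with px > 0.
glcm_mcc <- function(P, px, py) {
  keep <- px > 0
  if (sum(keep) < 2L) return(1)
  Ps <- P[keep, keep, drop = FALSE]
  pxs <- px[keep]; pys <- py[keep]
  Q <- diag(1 / pxs) %*% Ps %*% diag(1 / pys) %*% t(Ps)
  ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
  sqrt(max(0, ev[2]))
}

#' Gray-level co-occurrence matrix features
#'
#' Builds symmetric GLCMs for the four in-plane directions at the given
#' pixel distance, normalizes each, computes the 24-feature set per
#' direction and averages over directions. No distance weighting is applied.
#'
#' @param discretized a `discretized_roi` whose `levels` element is a matrix
#'   (NA outside the ROI)
#' @param distance neighbour distance in pixels
#' @return named numeric vector of length 24
#' @export
glcm_features <- function(discretized, distance = 1L) {
  L <- discretized$levels
  ng <- discretized$n_levels
  per_dir <- lapply(glcm_offsets(distance), function(off) {
    M <- glcm_matrix(L, ng, off)
    tot <- sum(M)
    if (tot == 0) return(NULL)     # direction with no valid pairs
    glcm_features_single(M / tot, ng)
  })
  per_dir <- Filter(Negate(is.null), per_dir)
  if (!length(per_dir)) {
    # single-pixel ROI: degenerate one-cell matrix values
    per_dir <- list(glcm_features_single(matrix(1, 1, 1), 1L))
  }
  Reduce(`+`, per_dir) / length(per_dir)
}
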