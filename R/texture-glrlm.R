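# Gray-level run-length matrix (GLRLM) features over the four in-plane
# directions; features computed per direction and averaged.

# Scan lines of a matrix along one of the 4 directions, as a list of vectors.
glrlm_lines <- function(L, direction) {
  switch(direction,
    "0,1"  = lapply(seq_len(nrow(L)), function(r) L[r, ]),
    "1,0"  = lapply(seq_len(ncol(L)), function(c) L[, c]),
    "1,1"  = split(L, col(L) - row(L)),
    "1,-1" = split(L, col(L) + row(L)),
    stop_radrobust("unknown direction"))
}

# Unnormalized run-length count matrix [level x run length] for one direction.
glrlm_matrix <- function(levels, n_levels, direction) {
  nmax <- max(dim(levels))
  counts <- numeric(n_levels * nmax)
  for (v in glrlm_lines(levels, direction)) {
    v <- as.vector(v)
    v[is.na(v)] <- 0L
    r <- rle(v)
    keep <- r$values > 0
    if (!any(keep)) next
    idx <- (r$values[keep] - 1L) * nmax + r$lengths[keep]
    counts <- counts + tabulate(idx, nbins = n_levels * nmax)
  }
  matrix(counts, n_levels, nmax, byrow = TRUE)
}

rlm_style_features <- function(P, n_pixels, prefix = c("Run", "Zone")) {
  # Shared feature algebra of run-length / size-zone style matrices:
  # P[i, j] counts (level i, length-or-size j) occurrences.
  iv <- seq_len(nrow(P)); jv <- seq_len(ncol(P))
  Ns <- sum(P)
  I <- matrix(iv, nrow(P), ncol(P)); J <- matrix(jv, nrow(P), ncol(P),
                                                 byrow = TRUE)
  pg <- rowSums(P); pl <- colSums(P)
  p <- P / Ns
  mu_i <- sum(I * p); mu_j <- sum(J * p)
  pn <- p[p > 0]
  list(
    small = sum(P / J^2) / Ns,
    large = sum(P * J^2) / Ns,
    gln = sum(pg^2) / Ns,
    glnn = sum(pg^2) / Ns^2,
    ln = sum(pl^2) / Ns,
    lnn = sum(pl^2) / Ns^2,
    pct = Ns / n_pixels,
    glv = sum((I - mu_i)^2 * p),
    lv = sum((J - mu_j)^2 * p),
    entropy = -sum(pn * log2(pn)),
    lgl = sum(P / I^2) / Ns,
    hgl = sum(P * I^2) / Ns,
    small_lgl = sum(P / (I^2 * J^2)) / Ns,
    small_hgl = sum(P * I^2 / J^2) / Ns,
    large_lgl = sum(P * J^2 / I^2) / Ns,
    large_hgl = sum(P * I^2 * J^2) / Ns
  )
}

glrlm_features_single <- function(P, n_pixels) {
  f <- rlm_style_features(P, n_pixels)
  c(
    GrayLevelNonUniformity = f$gln,
    GrayLevelNonUniformityNormalized = f$glnn,
    GrayLevelVariance = f$glv,
    HighGrayLevelRunEmphasis = f$hgl,
    LongRunEmphasis = f$large,
    LongRunHighGrayLevelEmphasis = f$large_hgl,
    LongRunLowGrayLevelEmphasis = f$large_lgl,
    LowGrayLevelRunEmphasis = f$lgl,
    RunEntropy = f$entropy,
    RunLengthNonUniformity = f$ln,
    RunLengthNonUniformityNormalized = f$lnn,
    RunPercentage = f$pct,
    RunVariance = f$lv,
    ShortRunEmphasis = f$small,
    ShortRunHighGrayLevelEmphasis = f$small_hgl,
    ShortRunLowGrayLevelEmphasis = f$small_lgl
  )
}

#' Gray-level run-length matrix features
#'
#' Run-length matrices are built for the four in-plane directions; the 16
#' features are computed per direction and averaged.
#' @inheritParams glcm_features
#' @return named numeric vector of length 16
#' @export
glrlm_features <- function(discretized) {
  L <- discretized$levels
  ng <- discretized$n_levels
  np <- sum(!is.na(L))
  dirs <- c("0,1", "1,0", "1,1", "1,-1")
  per_dir <- lapply(dirs, function(d) {
    M <- glrlm_matrix(L, ng, d)
    glrlm_features_single(M, np)
  })
  Reduce(`+`, per_dir) / length(per_dir)
}
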