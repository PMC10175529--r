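# Gray-level size-zone matrix (GLSZM) features. Zones are 8-connected
# components of equal gray level; a single matrix is built (no
# directionality).

# Label 8-connected equal-level zones with an iterative stack fill; returns
# a data frame of (level, size) per zone.
glszm_zones <- function(levels) {
  nr <- nrow(levels); nc <- ncol(levels)
  lab <- matrix(0L, nr, nc)
  nbr <- expand.grid(dr = -1:1, dc = -1:1)
  nbr <- nbr[!(nbr$dr == 0 & nbr$dc == 0), ]
  out_lev <- numeric(0); out_size <- integer(0)
  for (start in which(!is.na(levels))) {
    if (lab[start] != 0L) next
    r0 <- ((start - 1L) %% nr) + 1L
    c0 <- ((start - 1L) %/% nr) + 1L
    lv <- levels[r0, c0]
    stack <- start
    lab[start] <- 1L
    size <- 0L
    while (length(stack)) {
      cur <- stack[length(stack)]
      stack <- stack[-length(stack)]
      size <- size + 1L
      r <- ((cur - 1L) %% nr) + 1L
      c <- ((cur - 1L) %/% nr) + 1L
      rr <- r + nbr$dr; cc <- c + nbr$dc
      ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
      idx <- (cc[ok] - 1L) * nr + rr[ok]
      idx <- idx[!is.na(levels[idx]) & levels[idx] == lv & lab[idx] == 0L]
      if (length(idx)) {
        lab[idx] <- 1L
        stack <- c(stack, idx)
      }
    }
    out_lev <- c(out_lev, lv); out_size <- c(out_size, size)
  }
  data.frame(level = out_lev, size = out_size)
}

# Unnormalized size-zone count matrix [level x zone size].
glszm_matrix <- function(levels, n_levels) {
  z <- glszm_zones(levels)
  smax <- max(1L, z$size)
  counts <- tabulate((z$level - 1L) * smax + z$size, nbins = n_levels * smax)
  matrix(counts, n_levels, smax, byrow = TRUE)
}

#' Gray-level size-zone matrix features
#'
#' Zones are 8-connected components of pixels sharing a gray level; the
#' single (direction-free) matrix yields 16 features.
#' @inheritParams glcm_features
#' @return named numeric vector of length 16
#' @export
glszm_features <- function(discretized) {
  L <- discretized$levels
  np <- sum(!is.na(L))
  P <- glszm_matrix(L, discretized$n_levels)
  f <- rlm_style_features(P, np)
  c(
    GrayLevelNonUniformity = f$gln,
    GrayLevelNonUniformityNormalized = f$glnn,
    GrayLevelVariance = f$glv,
    HighGrayLevelZoneEmphasis = f$hgl,
    LargeAreaEmphasis = f$large,
    LargeAreaHighGrayLevelEmphasis = f$large_hgl,
    LargeAreaLowGrayLevelEmphasis = f$large_lgl,
    LowGrayLevelZoneEmphasis = f$lgl,
    SizeZoneNonUniformity = f$ln,
    SizeZoneNonUniformityNormalized = f$lnn,
    SmallAreaEmphasis = f$small,
    SmallAreaHighGrayLevelEmphasis = f$small_hgl,
    SmallAreaLowGrayLevelEmphasis = f$small_lgl,
    ZoneEntropy = f$entropy,
    ZonePercentage = f$pct,
    ZoneVariance = f$lv
  )
}
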