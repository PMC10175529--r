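# Neighborhood gray-tone difference matrix (NGTDM) features.
#
# For every in-ROI pixel the mean gray level of its valid (in-ROI)
# 8-neighbours is computed; s_i accumulates |i - neighbour mean| over pixels
# of level i, n_i counts them. Pixels with no valid neighbour are excluded.

ngtdm_table <- function(levels, n_levels, distance = 1L) {
  nr <- nrow(levels); nc <- ncol(levels)
  nb_sum <- matrix(0, nr, nc); nb_cnt <- matrix(0, nr, nc)
  offs <- expand.grid(dr = -distance:distance, dc = -distance:distance)
  offs <- offs[!(offs$dr == 0 & offs$dc == 0), ]
  for (k in seq_len(nrow(offs))) {
    dr <- offs$dr[k]; dc <- offs$dc[k]
    sh <- matrix(NA_real_, nr, nc)
    rs <- max(1L, 1L - dr):min(nr, nr - dr)
    cs <- max(1L, 1L - dc):min(nc, nc - dc)
    sh[rs, cs] <- levels[rs + dr, cs + dc]
    has <- !is.na(sh)
    nb_sum[has] <- nb_sum[has] + sh[has]
    nb_cnt <- nb_cnt + has
  }
  ok <- !is.na(levels) & nb_cnt > 0
  lev <- levels[ok]
  diffs <- abs(lev - nb_sum[ok] / nb_cnt[ok])
  n_i <- tabulate(lev, nbins = n_levels)
  s_i <- vapply(seq_len(n_levels),
                function(i) sum(diffs[lev == i]), numeric(1))
  list(n_i = n_i, s_i = s_i, n_valid = sum(ok))
}

#' Neighborhood gray-tone difference matrix features
#'
#' Coarseness, Contrast, Busyness, Complexity and Strength from the
#' per-level counts `n_i`, probabilities `p_i` and summed absolute
#' differences `s_i` between each pixel and the mean of its in-ROI
#' 8-neighbours.
#' @inheritParams glcm_features
#' @return named numeric vector of length 5
#' @export
ngtdm_features <- function(discretized, distance = 1L) {
  tb <- ngtdm_table(discretized$levels, discretized$n_levels, distance)
  n_i <- tb$n_i; s_i <- tb$s_i; N <- tb$n_valid
  p_i <- n_i / N
  act <- which(p_i > 0)
  ngp <- length(act)
  iv <- act
  coarse_den <- sum(p_i[act] * s_i[act])
  coarseness <- if (coarse_den > 0) 1 / coarse_den else 1e6
  contrast <- if (ngp > 1) {
    pij <- outer(p_i[act], p_i[act])
    dij2 <- outer(iv, iv, function(a, b) (a - b)^2)
    (sum(pij * dij2) / (ngp * (ngp - 1))) * (sum(s_i) / N)
  } else 0
  busy_den <- sum(abs(outer(iv * p_i[act], iv * p_i[act], "-")))
  busyness <- if (busy_den > 0) coarse_den / busy_den else 0
  complexity <- if (N > 0) {
    pi_m <- matrix(p_i[act], ngp, ngp)
    pj_m <- t(pi_m)
    si_m <- matrix(s_i[act], ngp, ngp)
    sj_m <- t(si_m)
    dij <- abs(outer(iv, iv, "-"))
    sum(dij * (pi_m * si_m + pj_m * sj_m) / (pi_m + pj_m)) / N
  } else 0
  strength_den <- sum(s_i)
  strength <- if (strength_den > 0) {
    pij_sum <- outer(p_i[act], p_i[act], "+")
    dij2 <- outer(iv, iv, function(a, b) (a - b)^2)
    sum(pij_sum * dij2) / strength_den
  } else 0
  c(Busyness = busyness, Coarseness = coarseness, Complexity = complexity,
    Contrast = contrast, Strength = strength)
}
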