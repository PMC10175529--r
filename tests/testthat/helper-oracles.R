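# Independent brute-force oracles for the texture-matrix builders. These
# enumerate the defining pairs/runs/zones/neighbourhoods directly, pixel by
# pixel, sharing no code with the implementations they check.

oracle_glcm <- function(levels, n_levels, offset) {
  nr <- nrow(levels); nc <- ncol(levels)
  M <- matrix(0, n_levels, n_levels)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    r2 <- r + offset[1]; c2 <- c + offset[2]
    if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
    i <- levels[r, c]; j <- levels[r2, c2]
    if (is.na(i) || is.na(j)) next
    M[i, j] <- M[i, j] + 1
    M[j, i] <- M[j, i] + 1   # symmetric convention
  }
  M
}

# Runs along one direction by walking every maximal line pixel by pixel.
oracle_glrlm <- function(levels, n_levels, dir) {
  nr <- nrow(levels); nc <- ncol(levels)
  nmax <- max(nr, nc)
  M <- matrix(0, n_levels, nmax)
  starts <- switch(paste(dir, collapse = ","),
    "0,1" = cbind(seq_len(nr), 1L),
    "1,0" = cbind(1L, seq_len(nc)),
    "1,1" = rbind(cbind(seq_len(nr), 1L), cbind(1L, 2:nc)),
    "1,-1" = rbind(cbind(seq_len(nr), nc), cbind(1L, seq_len(nc - 1L))))
  for (s in seq_len(nrow(starts))) {
    r <- starts[s, 1]; c <- starts[s, 2]
    cur <- NA; len <- 0L
    while (r >= 1 && r <= nr && c >= 1 && c <= nc) {
      v <- levels[r, c]
      if (!is.na(v) && !is.na(cur) && v == cur) {
        len <- len + 1L
      } else {
        if (!is.na(cur)) M[cur, len] <- M[cur, len] + 1
        cur <- v; len <- 1L
      }
      r <- r + dir[1]; c <- c + dir[2]
    }
    if (!is.na(cur)) M[cur, len] <- M[cur, len] + 1
  }
  M
}

# Zones by repeated neighbourhood expansion (no shared flood-fill code).
oracle_glszm_zones <- function(levels) {
  nr <- nrow(levels); nc <- ncol(levels)
  remaining <- which(!is.na(levels))
  zones <- list()
  while (length(remaining)) {
    seedpix <- remaining[1]
    lv <- levels[seedpix]
    zone <- seedpix
    grown <- TRUE
    while (grown) {
      grown <- FALSE
      for (p in setdiff(remaining, zone)) {
        if (levels[p] != lv) next
        pr <- (p - 1) %% nr + 1; pc <- (p - 1) %/% nr + 1
        for (z in zone) {
          zr <- (z - 1) %% nr + 1; zc <- (z - 1) %/% nr + 1
          if (abs(pr - zr) <= 1 && abs(pc - zc) <= 1) {
            zone <- c(zone, p); grown <- TRUE; break
          }
        }
      }
    }
    zones[[length(zones) + 1]] <- c(level = lv, size = length(zone))
    remaining <- setdiff(remaining, zone)
  }
  do.call(rbind, zones)
}

oracle_glszm <- function(levels, n_levels) {
  z <- oracle_glszm_zones(levels)
  smax <- max(z[, "size"])
  M <- matrix(0, n_levels, smax)
  for (k in seq_len(nrow(z)))
    M[z[k, "level"], z[k, "size"]] <- M[z[k, "level"], z[k, "size"]] + 1
  M
}

oracle_gldm <- function(levels, n_levels, alpha = 0, distance = 1) {
  nr <- nrow(levels); nc <- ncol(levels)
  recs <- NULL
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    v <- levels[r, c]
    if (is.na(v)) next
    dep <- 0L
    for (dr in -distance:distance) for (dc in -distance:distance) {
      if (dr == 0 && dc == 0) next
      r2 <- r + dr; c2 <- c + dc
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      w <- levels[r2, c2]
      if (!is.na(w) && abs(v - w) <= alpha) dep <- dep + 1L
    }
    recs <- rbind(recs, c(v, dep + 1L))
  }
  dmax <- max(recs[, 2])
  M <- matrix(0, n_levels, dmax)
  for (k in seq_len(nrow(recs)))
    M[recs[k, 1], recs[k, 2]] <- M[recs[k, 1], recs[k, 2]] + 1
  M
}

# Per-level n_i and s_i by direct per-pixel neighbourhood means.
oracle_ngtdm <- function(levels, n_levels, distance = 1) {
  nr <- nrow(levels); nc <- ncol(levels)
  n_i <- numeric(n_levels); s_i <- numeric(n_levels)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    v <- levels[r, c]
    if (is.na(v)) next
    nbrs <- c()
    for (dr in -distance:distance) for (dc in -distance:distance) {
      if (dr == 0 && dc == 0) next
      r2 <- r + dr; c2 <- c + dc
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      w <- levels[r2, c2]
      if (!is.na(w)) nbrs <- c(nbrs, w)
    }
    if (!length(nbrs)) next
    n_i[v] <- n_i[v] + 1
    s_i[v] <- s_i[v] + abs(v - mean(nbrs))
  }
  list(n_i = n_i, s_i = s_i)
}

# Random discretized test grid: size between 3x3 and 8x8, Ng <= max_levels,
# with optional NA holes mimicking a circular-ROI bounding box.
random_level_grid <- function(max_levels = 5, with_na = TRUE) {
  nr <- sample(3:8, 1); nc <- sample(3:8, 1)
  ng <- sample(2:max_levels, 1)
  g <- matrix(sample(seq_len(ng), nr * nc, replace = TRUE), nr, nc)
  if (with_na && stats::runif(1) < 0.5) {
    nhole <- sample(0:3, 1)
    if (nhole > 0) g[sample(length(g), nhole)] <- NA
  }
  list(levels = g, n_levels = ng)
}

as_disc <- function(levels, n_levels) {
  structure(list(levels = levels, n_levels = n_levels, bin_width = 1,
                 min_value = 1), class = "discretized_roi")
}
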