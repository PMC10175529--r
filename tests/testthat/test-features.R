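test_that("fixed-bin-width discretization follows the floor rule", {
  d <- discretize(c(0, 24.9, 25, 50), bin_width = 25)
  expect_equal(unname(d$levels), c(1, 1, 2, 3))
  expect_equal(d$n_levels, 3L)
  expect_equal(d$min_value, 0)
  const <- discretize(rep(12.3, 9), 25)
  expect_equal(const$n_levels, 1L)
  expect_true(all(const$levels == 1))
  # conservation: histogram over levels accounts for every pixel
  set.seed(5)
  x <- rnorm(400, 0, 40)
  dd <- discretize(x, 25)
  expect_equal(sum(tabulate(dd$levels, dd$n_levels)), 400L)
  expect_equal(max(dd$levels), dd$n_levels)
  expect_error(discretize(x, 0))
  expect_error(discretize(x, -5))
})

test_that("first-order features match hand computation and a direct-summation oracle", {
  f <- first_order_features(c(1, 2, 3, 4))
  expect_equal(f[["Mean"]], 2.5)
  expect_equal(f[["Variance"]], 1.25)              # population moments
  expect_equal(f[["RootMeanSquared"]], sqrt(7.5))
  expect_equal(f[["StandardDeviation"]], sqrt(1.25))
  expect_equal(f[["Energy"]], 30)
  expect_equal(f[["TotalEnergy"]], 30 * (500 / 512)^2 * 5)
  expect_length(f, 19L)
  # independent direct-summation oracle on random data
  set.seed(8)
  for (rep in 1:20) {
    x <- rnorm(sample(5:60, 1), sample(-50:50, 1), runif(1, 0.5, 30))
    n <- length(x)
    g <- first_order_features(x)
    mu <- sum(x) / n
    m2 <- sum((x - mu)^2) / n
    expect_equal(g[["Mean"]], mu, tolerance = 1e-12)
    expect_equal(g[["Variance"]], m2, tolerance = 1e-12)
    expect_equal(g[["MeanAbsoluteDeviation"]], sum(abs(x - mu)) / n,
                 tolerance = 1e-12)
    expect_equal(g[["Skewness"]], (sum((x - mu)^3) / n) / m2^1.5,
                 tolerance = 1e-10)
    expect_equal(g[["Kurtosis"]], (sum((x - mu)^4) / n) / m2^2,
                 tolerance = 1e-10)
    expect_equal(g[["Range"]], max(x) - min(x))
    expect_equal(g[["Median"]], median(x))
  }
  expect_error(first_order_features(numeric(0)))
})

test_that("constant ROIs yield the documented degenerate first-order values", {
  f <- first_order_features(rep(42, 100))
  expect_equal(f[["Mean"]], 42)
  expect_equal(f[["Median"]], 42)
  expect_equal(f[["Minimum"]], 42)
  expect_equal(f[["Maximum"]], 42)
  expect_equal(f[["Variance"]], 0)
  expect_equal(f[["Entropy"]], 0)
  expect_equal(f[["Uniformity"]], 1)
  expect_equal(f[["Skewness"]], 0)
  expect_equal(f[["Kurtosis"]], 0)
  expect_false(any(is.na(f)))
})

test_that("every texture matrix builder equals its brute-force oracle", {
  set.seed(2024)
  pad0 <- function(m, k) cbind(m, matrix(0, nrow(m), k - ncol(m)))
  for (it in 1:200) {
    g <- random_level_grid()
    L <- g$levels; ng <- g$n_levels
    if (all(is.na(L))) next
    for (off in list(c(0L, 1L), c(1L, 1L), c(1L, 0L), c(1L, -1L))) {
      expect_identical(radrobust:::glcm_matrix(L, ng, off) * 1,
                       oracle_glcm(L, ng, off) * 1)
      dn <- paste(off, collapse = ",")
      expect_identical(radrobust:::glrlm_matrix(L, ng, dn) * 1,
                       oracle_glrlm(L, ng, off) * 1)
    }
    a <- radrobust:::glszm_matrix(L, ng); b <- oracle_glszm(L, ng)
    k <- max(ncol(a), ncol(b))
    expect_identical(pad0(a, k) * 1, pad0(b, k) * 1)
    a <- radrobust:::gldm_matrix(L, ng); b <- oracle_gldm(L, ng)
    k <- max(ncol(a), ncol(b))
    expect_identical(pad0(a, k) * 1, pad0(b, k) * 1)
    nt <- radrobust:::ngtdm_table(L, ng); no <- oracle_ngtdm(L, ng)
    expect_equal(nt$n_i, no$n_i, ignore_attr = TRUE)
    expect_equal(nt$s_i, no$s_i, tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("texture matrices conserve pixel and pair counts", {
  set.seed(31)
  for (it in 1:50) {
    g <- random_level_grid()
    L <- g$levels; ng <- g$n_levels
    np <- sum(!is.na(L))
    if (np == 0) next
    for (off in list(c(0L, 1L), c(1L, 1L), c(1L, 0L), c(1L, -1L))) {
      M <- radrobust:::glcm_matrix(L, ng, off)
      if (sum(M) > 0) expect_equal(sum(M / sum(M)), 1, tolerance = 1e-12)
      dn <- paste(off, collapse = ",")
      R <- radrobust:::glrlm_matrix(L, ng, dn)
      lens <- matrix(seq_len(ncol(R)), ng, ncol(R), byrow = TRUE)
      expect_equal(sum(R * lens), np)        # runs partition the pixels
    }
    Z <- radrobust:::glszm_matrix(L, ng)
    sizes <- matrix(seq_len(ncol(Z)), ng, ncol(Z), byrow = TRUE)
    expect_equal(sum(Z * sizes), np)         # zones partition the pixels
    D <- radrobust:::gldm_matrix(L, ng)
    expect_equal(sum(D), np)                 # one dependence per pixel
    nt <- radrobust:::ngtdm_table(L, ng)
    expect_equal(sum(nt$n_i), nt$n_valid)
  }
})

test_that("worked texture examples hold", {
  # single-level ROI: one-cell co-occurrence matrix
  one <- as_disc(matrix(1, 4, 4), 1L)
  g1 <- glcm_features(one)
  expect_equal(g1[["JointEntropy"]], 0)
  expect_equal(g1[["MaximumProbability"]], 1)
  # 2x2 alternating columns: direction (0,1) pairs all (1,2); contrast 1
  L <- matrix(c(1, 1, 2, 2), 2, 2)
  M <- radrobust:::glcm_matrix(L, 2L, c(0L, 1L))
  expect_identical(M * 1, oracle_glcm(L, 2L, c(0L, 1L)) * 1)
  P <- M / sum(M)
  f <- radrobust:::glcm_features_single(P, 2L)
  expect_equal(f[["Contrast"]], 1)
  # constant row: single run of length n in the row direction
  row5 <- matrix(1, 1, 5)
  R <- radrobust:::glrlm_matrix(row5, 1L, "0,1")
  expect_equal(R[1, 5], 1)
  expect_equal(sum(R), 1)
  # checkerboard: 8-connectivity joins each colour diagonally -> 2 zones of 8
  cb <- as_disc((outer(1:4, 1:4, "+") %% 2) + 1, 2L)
  Z <- radrobust:::glszm_matrix(cb$levels, 2L)
  expect_equal(Z[1, 8], 1)
  expect_equal(Z[2, 8], 1)
  expect_equal(sum(Z), 2)
  # constant 3x3: only the centre pixel has all 8 neighbours dependent
  D <- radrobust:::gldm_matrix(matrix(1, 3, 3), 1L)
  expect_equal(D[1, 9], 1)
  # constant ROI: all NGTDM differences vanish
  n5 <- ngtdm_features(as_disc(matrix(3, 5, 5), 3L))
  expect_equal(n5[["Contrast"]], 0)
  expect_equal(unname(radrobust:::ngtdm_table(matrix(3, 5, 5), 3L)$s_i),
               c(0, 0, 0))
})

test_that("direction-averaged GLCM/GLRLM features are rotation invariant", {
  rot90 <- function(m) t(m)[, nrow(m):1, drop = FALSE]
  set.seed(77)
  for (it in 1:20) {
    n <- sample(4:7, 1)
    ng <- sample(2:4, 1)
    L <- matrix(sample(seq_len(ng), n * n, replace = TRUE), n, n)
    a <- as_disc(L, ng); b <- as_disc(rot90(L), ng)
    expect_equal(glcm_features(a), glcm_features(b), tolerance = 1e-12)
    expect_equal(glrlm_features(a), glrlm_features(b), tolerance = 1e-12)
  }
})

test_that("a constant ROI produces a finite, degenerate-valued 94-feature panel", {
  g <- matrix(100, 9, 9)
  g[1, 1] <- NA   # ragged corner, still constant inside
  df <- radrobust:::extract_panel_grid(g, extraction_config(), 1)
  expect_equal(nrow(df), 94L)
  expect_true(all(is.finite(df$value)))
  val <- function(cl, nm) df$value[df$feature_class == cl & df$feature_name == nm]
  expect_equal(val("firstorder", "Entropy"), 0)
  expect_equal(val("firstorder", "Uniformity"), 1)
  expect_equal(val("glcm", "JointEntropy"), 0)
  # a constant region is one zone: zone-size entropy collapses to 0 (run
  # lengths still vary line by line, so RunEntropy legitimately does not)
  expect_equal(val("glszm", "ZoneEntropy"), 0)
  expect_equal(val("ngtdm", "Contrast"), 0)
})

test_that("the panel composition is 19/24/14/16/16/5 over six classes", {
  p <- feature_panel()
  expect_equal(nrow(p), 94L)
  cnt <- table(p$feature_class)
  expect_equal(unname(cnt[c("firstorder", "glcm", "gldm", "glrlm",
                            "glszm", "ngtdm")]),
               c(19L, 24L, 14L, 16L, 16L, 5L), ignore_attr = TRUE)
  expect_false(anyDuplicated(paste(p$feature_class, p$feature_name)) > 0)
})
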