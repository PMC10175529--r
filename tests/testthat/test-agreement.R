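test_that("Bland-Altman reproduces identity, degenerate and outlier cases", {
  x <- c(3, 1, 4, 1, 5, 9, 2, 6)
  ba <- bland_altman(x, x)
  expect_equal(ba$bias, 0)
  expect_equal(ba$frac_within, 1)
  expect_true(ba$repeatable)
  expect_equal(ba$p_bias, 1)
  # constant non-zero differences: degenerate limits collapse onto the bias
  ba2 <- bland_altman(rep(0, 4), rep(1, 4))
  expect_equal(ba2$bias, 1)
  expect_equal(ba2$sd_diff, 0)
  expect_equal(ba2$frac_within, 1)
  expect_equal(ba2$p_bias, 0)
  # one extreme outlier among 16: 15/16 within the self-derived limits
  set.seed(42)
  d <- c(rnorm(15), 10)
  ba3 <- bland_altman(rep(0, 16), d)
  inside <- sum(d >= ba3$loa_low & d <= ba3$loa_high)   # direct count
  expect_equal(ba3$frac_within, inside / 16)
  expect_equal(ba3$frac_within, 15 / 16)
  expect_true(ba3$repeatable)
  # outliers at both ends: 14/16 fails the 90% cutoff
  d4 <- c(rnorm(14), 10, -10)
  ba4 <- bland_altman(rep(0, 16), d4)
  expect_equal(ba4$frac_within, 14 / 16)
  expect_false(ba4$repeatable)
  expect_error(bland_altman(1:4, 1:5))
  expect_error(bland_altman(1:2, 1:2))
})

test_that("CV matches hand-derived values and uses the absolute mean", {
  expect_equal(as.numeric(cv_pct(c(90, 100, 110))), 10)
  expect_equal(as.numeric(cv_pct(c(-90, -100, -110))), 10)
  expect_equal(as.numeric(cv_pct(rep(3, 5))), 0)
  z <- cv_pct(c(-1, 1, -1, 1))
  expect_true(is.infinite(as.numeric(z)))
  expect_true(is_degenerate(z))
  # positive-scale invariance, translation non-invariance
  set.seed(1)
  v <- rnorm(10, 50, 5)
  expect_equal(as.numeric(cv_pct(v * 3.7)), as.numeric(cv_pct(v)),
               tolerance = 1e-12)
  expect_false(isTRUE(all.equal(as.numeric(cv_pct(v + 100)),
                                as.numeric(cv_pct(v)))))
  expect_error(cv_pct(5))
})

test_that("QCD uses interpolated quartiles and is scale invariant", {
  expect_equal(as.numeric(qcd_pct(c(10, 20, 30, 40))), 30)  # Q1 17.5, Q3 32.5
  expect_equal(as.numeric(qcd_pct(rep(7, 6))), 0)
  set.seed(2)
  v <- rlnorm(12, 3, 0.4)
  expect_equal(as.numeric(qcd_pct(2 * v)), as.numeric(qcd_pct(v)),
               tolerance = 1e-12)
  z <- qcd_pct(c(-2, -1, 1, 2))
  expect_true(is.infinite(as.numeric(z)) && is_degenerate(z))
  expect_error(qcd_pct(1:3))
})

test_that("ICC(A,1) reproduces hand ANOVA and an independent aov oracle", {
  expect_equal(as.numeric(icc_a1(cbind(c(1, 2, 3), c(2, 3, 4)))), 2 / 3,
               tolerance = 1e-12)
  expect_equal(as.numeric(icc_a1(cbind(c(5, 7, 9, 11), c(5, 7, 9, 11)))), 1)
  dg <- icc_a1(matrix(4, 3, 2))
  expect_equal(as.numeric(dg), 1)
  expect_true(is_degenerate(dg))
  expect_error(icc_a1(matrix(c(1, 2, NA, 4, 5, 6), 3, 2)))
  # oracle: mean squares from a two-way aov decomposition
  icc_oracle <- function(m) {
    n <- nrow(m); k <- ncol(m)
    df <- data.frame(y = as.vector(m),
                     subj = factor(rep(seq_len(n), k)),
                     rater = factor(rep(seq_len(k), each = n)))
    tab <- summary(aov(y ~ subj + rater, data = df))[[1]]
    msr <- tab["subj", "Mean Sq"]; msc <- tab["rater", "Mean Sq"]
    mse <- tab["Residuals", "Mean Sq"]
    (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  }
  m1 <- cbind(c(1, 2, 3), c(3, 2, 1))
  expect_equal(as.numeric(icc_a1(m1)), icc_oracle(m1), tolerance = 1e-12)
  set.seed(12)
  for (it in 1:20) {
    m <- matrix(rnorm(16 * 2, 10, 3), 16, 2)
    m[, 2] <- m[, 2] + rnorm(16, 0.5, 1)
    expect_equal(as.numeric(icc_a1(m)), icc_oracle(m), tolerance = 1e-10)
  }
})

test_that("CCC matches Lin's formula and is bounded by Pearson correlation", {
  expect_equal(as.numeric(ccc(c(1, 2, 3), c(2, 3, 4))), 4 / 7,
               tolerance = 1e-12)
  expect_equal(as.numeric(ccc(c(4, 8, 15), c(4, 8, 15))), 1)
  dg <- ccc(rep(2, 5), rep(2, 5))
  expect_equal(as.numeric(dg), 1)
  expect_true(is_degenerate(dg))
  set.seed(3)
  for (it in 1:100) {
    x <- rnorm(16); y <- rnorm(16, 0.3 * x, 1)
    expect_lte(abs(as.numeric(ccc(x, y))), abs(cor(x, y)) + 1e-12)
  }
  expect_error(ccc(1:4, 1:5))
})

test_that("ICC and CCC agree for two raters and share affine invariance", {
  set.seed(21)
  for (it in 1:200) {
    x <- rnorm(16); y <- 0.8 * x + rnorm(16, 0, 0.6)
    expect_lt(abs(as.numeric(icc_a1(cbind(x, y))) - as.numeric(ccc(x, y))),
              0.05)
  }
  x <- rnorm(16); y <- x + rnorm(16, 0, 0.5)
  expect_equal(as.numeric(icc_a1(cbind(2.5 * x - 7, 2.5 * y - 7))),
               as.numeric(icc_a1(cbind(x, y))), tolerance = 1e-10)
  expect_equal(as.numeric(ccc(2.5 * x - 7, 2.5 * y - 7)),
               as.numeric(ccc(x, y)), tolerance = 1e-10)
})

test_that("Spearman correlation handles monotone data and ties like the rank oracle", {
  s <- spearman_cor(1:6, c(2, 4, 9, 16, 25, 36))
  expect_equal(s$rho, 1)
  expect_equal(s$rho_squared, 1)
  expect_equal(s$p, 0)
  expect_equal(spearman_cor(1:6, -(1:6))$rho, -1)
  # ties: brute-force average ranks then explicit Pearson formula
  x <- c(1, 2, 2, 3, 5, 5, 5, 9)
  y <- c(2, 1, 4, 4, 7, 6, 6, 10)
  avg_rank <- function(v)
    vapply(v, function(a) mean(which(sort(v) == a)), numeric(1))
  rx <- avg_rank(x); ry <- avg_rank(y)
  pearson <- function(a, b)
    sum((a - mean(a)) * (b - mean(b))) /
      sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  s2 <- spearman_cor(x, y)
  expect_equal(s2$rho, pearson(rx, ry), tolerance = 1e-12)
  expect_equal(s2$rho, unname(cor(x, y, method = "spearman")),
               tolerance = 1e-12)
  expect_error(spearman_cor(rep(1, 5), 1:5),
               class = "radrobust_degenerate_stat")
})

test_that("self-derived limits keep most Gaussian differences within them", {
  # with n = 16 Gaussian differences the expected within-limits fraction
  # exceeds 1 - 2/n, so the mean over many draws clears the 90% cutoff
  set.seed(99)
  fr <- vapply(1:1000, function(i) {
    bland_altman(rnorm(16), rnorm(16))$frac_within
  }, numeric(1))
  expect_gte(mean(fr), 0.90)
})
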