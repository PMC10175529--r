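test_that("default phantom spec matches the physical phantom layout", {
  spec <- default_phantom_spec()
  ins <- spec$inserts
  expect_equal(spec$disk_diameter_mm, 330)
  expect_equal(spec$insert_diameter_mm, 28)
  expect_equal(nrow(ins), 16L)
  expect_equal(sum(ins$kind == "iodine"), 5L)
  expect_equal(sum(ins$kind == "density_rod"), 11L)
  io <- ins$nominal_value[ins$kind == "iodine"]
  expect_true(all(io >= 2.0 & io <= 15.0))
  expect_true(min(io) == 2.0 && max(io) == 15.0)
  rod <- ins$nominal_value[ins$kind == "density_rod"]
  expect_true(all(rod >= 0.44 & rod <= 1.69))
  # non-overlap: all pairwise centre distances exceed the insert diameter
  d <- as.matrix(dist(ins[, c("x_mm", "y_mm")]))
  diag(d) <- Inf
  expect_true(all(d > 28))
  # all inserts fully inside the disk
  expect_true(all(sqrt(ins$x_mm^2 + ins$y_mm^2) + 14 <= 165))
})

test_that("platform models are deterministic with a zero-deviation reference", {
  a <- default_platform_models(10, seed = 7, spread_hu = 15)
  b <- default_platform_models(10, seed = 7, spread_hu = 15)
  expect_identical(a, b)
  expect_true(all(a[[1]]$hu_bias == 0))
  expect_true(all(a[[1]]$hu_insert_deviation == 0))
  expect_error(default_platform_models(1), class = "radrobust_config_error")
  # zero spread makes every platform identical to the reference
  z <- default_platform_models(10, seed = 7, spread_hu = 0)
  for (pl in z) {
    expect_true(all(pl$hu_bias == 0))
    expect_true(all(pl$hu_insert_deviation == 0))
    expect_equal(pl$kernel_fwhm_px, z[[1]]$kernel_fwhm_px)
    expect_equal(unname(pl$noise_sd), unname(z[[1]]$noise_sd))
  }
  # VMI deviations drawn with smaller spread than VUE
  devs <- do.call(rbind, lapply(a[-1], function(p) p$hu_insert_deviation))
  expect_lt(sd(devs[, "VMI70keV"]), sd(devs[, "VUE"]))
})

noiseless_platform <- function(bias = c(VUE = 0, VMI70keV = 0),
                               dev = cbind(VUE = rep(0, 16),
                                           VMI70keV = rep(0, 16))) {
  structure(list(platform_id = 99L, scanner_type = "dsDECT",
                 hu_bias = bias, hu_insert_deviation = dev,
                 noise_sd = c(VUE = 0, VMI70keV = 0),
                 kernel_fwhm_px = 0, air_hu = -1000),
            class = "platform_model")
}

test_that("noiseless rasterization reproduces analytic HU values exactly", {
  spec <- default_phantom_spec()
  dev <- cbind(VUE = seq(-8, 7), VMI70keV = seq(4, -11))
  pl <- noiseless_platform(bias = c(VUE = 5, VMI70keV = -3), dev = dev)
  for (ty in c("VUE", "VMI70keV")) {
    sc <- simulate_scan(spec, pl, ty, repeat_idx = 1, seed = 1)
    expect_equal(dim(sc$pixels), c(512L, 512L))
    expect_equal(sc$pixel_spacing_mm, 500 / 512)
    expect_identical(unname(sc$applied_shift_px), c(0, 0))
    s <- sc$pixel_spacing_mm
    hu <- spec$inserts[[paste0("hu_", ty)]] + pl$hu_bias[[ty]] + dev[, ty]
    for (i in 1:16) {
      r <- round(spec$inserts$y_mm[i] / s + 256.5)
      c <- round(spec$inserts$x_mm[i] / s + 256.5)
      expect_identical(sc$pixels[r, c], hu[i])
    }
    expect_identical(sc$pixels[256, 256], spec$background_hu)  # disk centre
    expect_identical(sc$pixels[1, 1], -1000)                   # air corner
  }
})

test_that("scans are pure functions of their seed and record repositioning", {
  spec <- default_phantom_spec()
  pl <- default_platform_models(3, seed = 2)[[2]]
  a <- simulate_scan(spec, pl, "VUE", 2, seed = 31)
  b <- simulate_scan(spec, pl, "VUE", 2, seed = 31)
  expect_identical(a$pixels, b$pixels)
  expect_identical(a$applied_shift_px, b$applied_shift_px)
  expect_true(all(abs(a$applied_shift_px) <= 3))
  expect_false(identical(
    a$pixels, simulate_scan(spec, pl, "VUE", 2, seed = 32)$pixels))
  expect_error(simulate_scan(spec, pl, "radiograph", 1, seed = 1))
})

test_that("recorded shifts re-align insert centroids to within 0.5 px", {
  spec <- default_phantom_spec()
  pl <- noiseless_platform()
  ref <- simulate_scan(spec, pl, "VMI70keV", 1, seed = 1)
  centroid <- function(img, hu) {
    w <- which(abs(img - hu) < 0.5, arr.ind = TRUE)
    colMeans(w)
  }
  hu1 <- spec$inserts$hu_VMI70keV[1]          # unique dense insert (990 HU)
  for (seed in c(5, 17, 23)) {
    sc <- simulate_scan(spec, pl, "VMI70keV", 2, seed = seed)
    sh <- sc$applied_shift_px
    c_ref <- centroid(ref$pixels, hu1)
    c_mov <- centroid(sc$pixels, hu1)
    # rows move with dy, columns with dx
    realigned <- c_mov - c(sh[["dy"]], sh[["dx"]])
    expect_lt(max(abs(realigned - c_ref)), 0.5)
  }
})

test_that("ROI means are unbiased with standard errors tracking the noise model", {
  spec <- default_phantom_spec()
  roi <- make_roi_masks(spec)
  n_px <- nrow(roi$stencil)
  base <- noiseless_platform()
  analytic <- spec$inserts$hu_VMI70keV[1]
  mk <- function(kern) {
    p <- base; p$noise_sd <- c(VUE = 10, VMI70keV = 10)
    p$kernel_fwhm_px <- kern
    p
  }
  run_means <- function(pl, nsim) {
    vapply(seq_len(nsim), function(s) {
      sc <- simulate_scan(spec, pl, "VMI70keV", 1, seed = 1000 + s)
      mean_ct_number(sc, roi, 1)
    }, numeric(1))
  }
  # unsmoothed: ROI mean unbiased for the analytic HU, SE = noise_sd/sqrt(N)
  m0 <- run_means(mk(0), 200)
  expect_lt(abs(mean(m0) - analytic), 0.5)
  se_expect <- 10 / sqrt(n_px)
  expect_lt(abs(sd(m0) - se_expect) / se_expect, 0.20)
  # smoothing correlates the noise: per-pixel SD shrinks markedly while the
  # ROI mean stays unbiased against the noiseless rendering of the same
  # platform, with a standard error no larger than the unsmoothed one (the
  # mass-preserving kernel leaves the ROI sum nearly unchanged)
  m2 <- run_means(mk(2), 120)
  ref2 <- simulate_scan(spec, base, "VMI70keV", 1, seed = 1)
  ref2$pixels <- radrobust:::smooth_gaussian(ref2$pixels, 2)
  noiseless_mean <- mean_ct_number(ref2, roi, 1)
  expect_lt(abs(mean(m2) - noiseless_mean), 0.5)
  expect_lt(sd(m2), sd(m0) * 1.1)
  # pixel-level noise attenuation is monotone in the kernel width
  pixel_sd <- vapply(c(0, 1, 2, 3), function(k) {
    sc <- simulate_scan(spec, mk(k), "VMI70keV", 1, seed = 55)
    sd(sc$pixels[200:312, 40:80])   # homogeneous disk region
  }, numeric(1))
  expect_true(all(diff(pixel_sd) < 0))
})

test_that("simulate_study writes a complete factorial with reproducible files", {
  spec <- default_phantom_spec()
  pls <- default_platform_models(2, seed = 4)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  man <- simulate_study(spec, pls, image_types = "VUE", n_repeats = 2,
                        seed = 5, out_dir = d1)
  expect_equal(nrow(man), 4L)           # 2 platforms x 1 type x 2 repeats
  expect_false(anyDuplicated(man$file_path) > 0)
  expect_true(all(file.exists(file.path(d1, man$file_path))))
  man2 <- simulate_study(spec, pls, image_types = "VUE", n_repeats = 2,
                         seed = 5, out_dir = d2)
  for (f in man$file_path)
    expect_identical(readBin(file.path(d1, f), "raw", 9e6),
                     readBin(file.path(d2, f), "raw", 9e6))
  expect_error(simulate_study(spec, pls, n_repeats = 1, out_dir = d1))
  # round-trip preserves HU to float32 precision and provenance via manifest
  sc <- read_scan_nifti(file.path(d1, man$file_path[1]),
                        man$platform_id[1], man$image_type[1],
                        man$repeat_idx[1])
  direct <- simulate_scan(spec, pls[[1]], "VUE", 1, seed = man$seed[1])
  expect_lt(max(abs(sc$pixels - direct$pixels)), 1e-3)
})
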