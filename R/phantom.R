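#' Phantom geometry: disk, inserts and reference CT numbers
#'
#' The simulated phantom is a 330 mm water-equivalent disk holding sixteen
#' 28 mm cylindrical inserts: five iodine solutions (2.0--15.0 mg/mL) and
#' eleven tissue-mimicking density rods (0.44--1.69 g/cm3). Each insert
#' carries a reference CT number (HU) per image type; on virtual unenhanced
#' (VUE) images the iodine signal is removed, so iodine inserts sit at
#' water-equivalent 0 HU, while on 70 keV virtual monoenergetic images
#' (VMI70keV) iodine enhances at roughly 25 HU per mg/mL.
#'
#' @param disk_diameter_mm disk diameter (mm)
#' @param insert_diameter_mm insert diameter (mm)
#' @param background_hu HU of the water-equivalent disk material
#' @param air_hu HU outside the phantom
#' @return an object of class `phantom_spec`: a list with the geometry and a
#'   data frame `inserts` (one row per insert: `insert_id`, `label`, `kind`,
#'   `nominal_value`, `x_mm`, `y_mm`, `hu_VUE`, `hu_VMI70keV`).
#' @details The hole layout is not prescribed by any standard; the default
#'   places ten inserts on an outer ring (radius 115 mm) and six on an inner
#'   ring (radius 60 mm), alternating high- and low-attenuation materials so
#'   that no two dense inserts are adjacent (beam-hardening-minimizing
#'   convention). All pairwise centre distances exceed the 28 mm insert
#'   diameter.
#' @export
default_phantom_spec <- function(disk_diameter_mm = 330,
                                 insert_diameter_mm = 28,
                                 background_hu = 0,
                                 air_hu = -1000) {
  outer_r <- 115; inner_r <- 60
  ang_out <- (0:9) * 2 * pi / 10
  ang_in <- pi / 6 + (0:5) * 2 * pi / 6
  # label, kind, nominal (mg/mL iodine or g/cm3 rod), HU on VUE, HU on VMI70keV
  mat <- rbind(
    data.frame(label = "cortical_bone_1.69", kind = "density_rod", nominal_value = 1.69,  hu = 990),
    data.frame(label = "lung_LN450_0.44",    kind = "density_rod", nominal_value = 0.44,  hu = -540),
    data.frame(label = "cb2_50pct_1.56",     kind = "density_rod", nominal_value = 1.56,  hu = 800),
    data.frame(label = "adipose_0.92",       kind = "density_rod", nominal_value = 0.92,  hu = -90),
    data.frame(label = "cb2_30pct_1.33",     kind = "density_rod", nominal_value = 1.33,  hu = 450),
    data.frame(label = "breast_0.98",        kind = "density_rod", nominal_value = 0.98,  hu = -40),
    data.frame(label = "iodine_15.0",        kind = "iodine",      nominal_value = 15.0,  hu = NA),
    data.frame(label = "solid_water_1.015",  kind = "density_rod", nominal_value = 1.015, hu = 0),
    data.frame(label = "iodine_10.0",        kind = "iodine",      nominal_value = 10.0,  hu = NA),
    data.frame(label = "brain_1.05",         kind = "density_rod", nominal_value = 1.05,  hu = 30),
    data.frame(label = "iodine_7.5",         kind = "iodine",      nominal_value = 7.5,   hu = NA),
    data.frame(label = "liver_1.10",         kind = "density_rod", nominal_value = 1.10,  hu = 90),
    data.frame(label = "iodine_5.0",         kind = "iodine",      nominal_value = 5.0,   hu = NA),
    data.frame(label = "bone_B200_1.15",     kind = "density_rod", nominal_value = 1.15,  hu = 230),
    data.frame(label = "iodine_2.0",         kind = "iodine",      nominal_value = 2.0,   hu = NA),
    data.frame(label = "inner_bone_1.14",    kind = "density_rod", nominal_value = 1.14,  hu = 210)
  )
  x <- c(outer_r * cos(ang_out), inner_r * cos(ang_in))
  y <- c(outer_r * sin(ang_out), inner_r * sin(ang_in))
  iodine <- mat$kind == "iodine"
  hu_vmi <- ifelse(iodine, 25 * mat$nominal_value, mat$hu)
  hu_vue <- ifelse(iodine, 0, mat$hu)
  inserts <- data.frame(
    insert_id = seq_len(16L), label = mat$label, kind = mat$kind,
    nominal_value = mat$nominal_value, x_mm = x, y_mm = y,
    hu_VUE = hu_vue, hu_VMI70keV = hu_vmi,
    stringsAsFactors = FALSE
  )
  structure(
    list(disk_diameter_mm = disk_diameter_mm,
         insert_diameter_mm = insert_diameter_mm,
         background_hu = background_hu,
         air_hu = air_hu,
         inserts = inserts),
    class = "phantom_spec"
  )
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("Phantom: %.0f mm disk, %d inserts of %.0f mm (%d iodine, %d rods)\n",
              x$disk_diameter_mm, nrow(x$inserts), x$insert_diameter_mm,
              sum(x$inserts$kind == "iodine"),
              sum(x$inserts$kind == "density_rod")))
  invisible(x)
}

reference_hu <- function(spec, image_type) {
  check_image_type(image_type)
  spec$inserts[[paste0("hu_", image_type)]]
}

validate_phantom_spec <- function(spec) {
  ins <- spec$inserts
  if (nrow(ins) != 16L) stop_radrobust("phantom must have 16 inserts")
  rad <- sqrt(ins$x_mm^2 + ins$y_mm^2)
  if (any(rad + spec$insert_diameter_mm / 2 > spec$disk_diameter_mm / 2))
    stop_radrobust("insert extends beyond disk")
  d <- as.matrix(stats::dist(ins[, c("x_mm", "y_mm")]))
  diag(d) <- Inf
  if (any(d <= spec$insert_diameter_mm))
    stop_radrobust("inserts overlap or touch")
  invisible(spec)
}

#' Surrogate models for DECT imaging platforms
#'
#' Each platform is an abstraction of one scanner/protocol combination: a
#' global HU bias, per-insert HU deviations, Gaussian noise and a
#' reconstruction-kernel-like smoothing FWHM, per image type. Platform 1 is
#' the reference (zero bias and deviations). Deviations for VMI70keV are
#' drawn with a smaller spread than for VUE (`vmi_factor`), reflecting the
#' lower CT-number variability of monoenergetic images across platforms.
#' Kernel and noise heterogeneity across platforms scales linearly with
#' `spread_hu`, so `spread_hu = 0` yields platforms identical to the
#' reference.
#'
#' @param n_platforms number of platforms (>= 2)
#' @param seed integer seed; output is a pure function of the arguments
#' @param spread_hu SD (HU) of per-insert CT-number deviations on VUE images
#' @param vmi_factor multiplier (< 1) applied to `spread_hu` for VMI70keV
#' @param bias_sd SD (HU) of the global per-platform bias; default `spread_hu/2`
#' @param noise_sd baseline image noise SD in HU
#' @param kernel_fwhm_px baseline smoothing kernel FWHM in pixels
#' @param hetero_inserts optional integer vector of insert ids whose
#'   deviations are inflated by `hetero_scale` (heterogeneous-offset designs)
#' @param hetero_scale multiplier for `hetero_inserts` deviations
#' @return list of `platform_model` objects
#' @export
default_platform_models <- function(n_platforms = 10L, seed = 1L,
                                    spread_hu = 15, vmi_factor = 0.5,
                                    bias_sd = NULL, noise_sd = 10,
                                    kernel_fwhm_px = 2,
                                    hetero_inserts = NULL, hetero_scale = 1) {
  if (n_platforms < 2L)
    stop_radrobust("n_platforms must be >= 2", class = "radrobust_config_error")
  if (spread_hu < 0) stop_radrobust("spread_hu must be >= 0")
  bias_sd <- bias_sd %||% (spread_hu / 2)
  # scanner-type pattern mirroring a 6 dual-source / 3 kV-switching /
  # 1 dual-layer fleet
  types <- rep(c(rep("dsDECT", 6), rep("rsDECT", 3), "dlDECT"),
               length.out = n_platforms)
  jitter_frac <- if (spread_hu > 0) spread_hu / 15 else 0
  with_seed(seed, {
    lapply(seq_len(n_platforms), function(p) {
      if (p == 1L) {
        bias <- c(VUE = 0, VMI70keV = 0)
        dev <- cbind(VUE = rep(0, 16), VMI70keV = rep(0, 16))
        kern <- kernel_fwhm_px
        nsd <- c(VUE = noise_sd, VMI70keV = noise_sd)
      } else {
        bias <- c(VUE = stats::rnorm(1, 0, bias_sd),
                  VMI70keV = stats::rnorm(1, 0, bias_sd * vmi_factor))
        dv <- stats::rnorm(16, 0, spread_hu)
        dm <- stats::rnorm(16, 0, spread_hu * vmi_factor)
        if (!is.null(hetero_inserts)) {
          dv[hetero_inserts] <- dv[hetero_inserts] * hetero_scale
          dm[hetero_inserts] <- dm[hetero_inserts] * hetero_scale
        }
        dev <- cbind(VUE = dv, VMI70keV = dm)
        kern <- kernel_fwhm_px *
          (1 + 0.25 * jitter_frac * stats::runif(1, -1, 1))
        nj <- 1 + 0.2 * jitter_frac * stats::runif(1, -1, 1)
        nsd <- c(VUE = noise_sd * nj, VMI70keV = noise_sd * nj)
      }
      structure(
        list(platform_id = p, scanner_type = types[p],
             hu_bias = bias, hu_insert_deviation = dev,
             noise_sd = nsd, kernel_fwhm_px = kern, air_hu = -1000),
        class = "platform_model"
      )
    })
  })
}

#' A noiseless, unbiased platform (used as registration reference)
#' @export
reference_platform <- function() {
  structure(
    list(platform_id = 0L, scanner_type = "reference",
         hu_bias = c(VUE = 0, VMI70keV = 0),
         hu_insert_deviation = cbind(VUE = rep(0, 16), VMI70keV = rep(0, 16)),
         noise_sd = c(VUE = 1e-12, VMI70keV = 1e-12),
         kernel_fwhm_px = 0, air_hu = -1000),
    class = "platform_model"
  )
}

#' @export
print.platform_model <- function(x, ...) {
  cat(sprintf(
    "Platform %d (%s): bias VUE %+.1f / VMI %+.1f HU, noise %.1f HU, kernel %.2f px\n",
    x$platform_id, x$scanner_type, x$hu_bias[["VUE"]],
    x$hu_bias[["VMI70keV"]], x$noise_sd[["VUE"]], x$kernel_fwhm_px))
  invisible(x)
}

#' Simulate one reconstructed phantom slice
#'
#' Rasterizes the phantom on a 512 x 512 grid over a 500 x 500 mm field of
#' view (pixel spacing 500/512 = 0.9766 mm). Inside an insert the pixel value
#' is `reference_hu + platform bias + per-insert deviation`; elsewhere inside
#' the disk it is `background_hu`, and `air_hu` outside. For `repeat_idx > 1`
#' the phantom is rigidly repositioned by a random shift uniform in +/- 3 px
#' per axis (recorded in `applied_shift_px`); repeat 1 uses zero shift.
#' Gaussian noise (SD `noise_sd`) is added and the image is then smoothed
#' with a Gaussian kernel of FWHM `kernel_fwhm_px`, which emulates the
#' spatially correlated noise of reconstruction kernels. The result is a pure
#' function of `(spec, platform, image_type, repeat_idx, seed)`.
#'
#' @param spec a `phantom_spec`
#' @param platform a `platform_model`
#' @param image_type `"VUE"` or `"VMI70keV"`
#' @param repeat_idx scan repeat number (1 = first positioning)
#' @param seed integer seed for shift and noise
#' @param shift_px optional explicit `(dx, dy)` pixel shift overriding the
#'   random repositioning (dx = column, dy = row)
#' @param matrix_size reconstruction matrix (512)
#' @param fov_mm scan field of view (500 mm)
#' @return object of class `scan_image`
#' @export
simulate_scan <- function(spec, platform, image_type, repeat_idx = 1L,
                          seed = 1L, shift_px = NULL,
                          matrix_size = 512L, fov_mm = 500) {
  check_image_type(image_type)
  validate_phantom_spec(spec)
  s <- fov_mm / matrix_size
  n <- matrix_size
  ref_hu <- reference_hu(spec, image_type)
  bias <- platform$hu_bias[[image_type]]
  dev <- platform$hu_insert_deviation[, image_type]
  nsd <- platform$noise_sd[[image_type]]
  with_seed(seed, {
    if (is.null(shift_px)) {
      shift_px <- if (repeat_idx > 1L) stats::runif(2, -3, 3) else c(0, 0)
    }
    dx <- shift_px[1]; dy <- shift_px[2]
    cx_mm <- dx * s; cy_mm <- dy * s   # phantom centre after repositioning
    coord <- (seq_len(n) - (n + 1) / 2) * s   # pixel-centre coordinates (mm)
    # squared distance to the (shifted) disk centre; rows = y, cols = x
    dy2 <- (coord - cy_mm)^2
    dx2 <- (coord - cx_mm)^2
    r2 <- outer(dy2, dx2, "+")
    img <- matrix(platform$air_hu, n, n)
    img[r2 <= (spec$disk_diameter_mm / 2)^2] <- spec$background_hu
    ins_r2 <- (spec$insert_diameter_mm / 2)^2
    for (i in seq_len(nrow(spec$inserts))) {
      ix <- spec$inserts$x_mm[i] + cx_mm
      iy <- spec$inserts$y_mm[i] + cy_mm
      rr <- outer((coord - iy)^2, (coord - ix)^2, "+")
      img[rr <= ins_r2] <- ref_hu[i] + bias + dev[i]
    }
    if (nsd > 1e-9)
      img <- img + matrix(stats::rnorm(n * n, 0, nsd), n, n)
    img <- smooth_gaussian(img, platform$kernel_fwhm_px)
    structure(
      list(pixels = img, pixel_spacing_mm = s,
           platform_id = platform$platform_id, image_type = image_type,
           repeat_idx = as.integer(repeat_idx),
           applied_shift_px = c(dx = dx, dy = dy),
           seed_used = as.integer(seed)),
      class = "scan_image"
    )
  })
}

#' @export
print.scan_image <- function(x, ...) {
  cat(sprintf(
    "ScanImage %dx%d @ %.4f mm | platform %d %s repeat %d | shift (%.2f, %.2f) px\n",
    nrow(x$pixels), ncol(x$pixels), x$pixel_spacing_mm, x$platform_id,
    x$image_type, x$repeat_idx, x$applied_shift_px[1], x$applied_shift_px[2]))
  invisible(x)
}

#' Noiseless reference rendering used as registration target
#' @param spec a `phantom_spec`
#' @param image_type image type to render
#' @inheritParams simulate_scan
#' @export
render_reference <- function(spec, image_type = "VMI70keV",
                             matrix_size = 512L, fov_mm = 500) {
  simulate_scan(spec, reference_platform(), image_type,
                repeat_idx = 1L, seed = 0L, shift_px = c(0, 0),
                matrix_size = matrix_size, fov_mm = fov_mm)
}

#' Simulate a complete multi-platform, multi-repeat study to disk
#'
#' Writes one NIfTI image per (platform, image type, repeat) combination,
#' with per-scan seeds derived deterministically from the master seed, plus a
#' manifest CSV describing every file.
#'
#' @param spec a `phantom_spec`
#' @param platforms list of `platform_model`s
#' @param image_types character vector of image types
#' @param n_repeats repeats per platform/type (>= 2 for test-retest)
#' @param seed master seed
#' @param out_dir output directory (created if absent)
#' @return invisibly, the manifest data frame (also written as
#'   `manifest.csv`): columns `file_path`, `platform_id`, `image_type`,
#'   `repeat_idx`, `seed`, `dx_px`, `dy_px`.
#' @export
simulate_study <- function(spec, platforms, image_types = image_types_all(),
                           n_repeats = 2L, seed = 1L, out_dir) {
  if (n_repeats < 2L)
    stop_radrobust("n_repeats must be >= 2 (test-retest requires a rescan)")
  if (!dir.exists(out_dir) &&
        !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop_radrobust("cannot create out_dir: ", out_dir,
                   class = "radrobust_io_error")
  rows <- list()
  for (pl in platforms) for (ty in image_types) for (rp in seq_len(n_repeats)) {
    sseed <- derive_scan_seed(seed, pl$platform_id, ty, rp)
    sc <- simulate_scan(spec, pl, ty, repeat_idx = rp, seed = sseed)
    fn <- sprintf("scan_p%02d_%s_r%d.nii.gz", pl$platform_id, ty, rp)
    path <- file.path(out_dir, fn)
    write_scan_nifti(sc, path)
    rows[[length(rows) + 1L]] <- data.frame(
      file_path = fn, platform_id = pl$platform_id, image_type = ty,
      repeat_idx = rp, seed = sseed,
      dx_px = sc$applied_shift_px[["dx"]], dy_px = sc$applied_shift_px[["dy"]],
      stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

#' Write / read a scan as NIfTI-1
#'
#' HU values are stored as float32 with the in-plane pixel spacing in the
#' header.
#' @param scan a `scan_image`
#' @param path output `.nii` / `.nii.gz` path
#' @export
write_scan_nifti <- function(scan, path) {
  arr <- scan$pixels
  attr(arr, "pixdim") <- c(scan$pixel_spacing_mm, scan$pixel_spacing_mm)
  attr(arr, "pixunits") <- "mm"
  RNifti::writeNifti(RNifti::asNifti(arr, datatype = "float"), path)
  invisible(path)
}

#' @rdname write_scan_nifti
#' @param platform_id,image_type,repeat_idx provenance to attach (e.g. from a
#'   manifest row)
#' @export
read_scan_nifti <- function(path, platform_id = NA_integer_,
                            image_type = "VMI70keV", repeat_idx = 1L) {
  img <- RNifti::readNifti(path)
  px <- as.matrix(img[, ])
  structure(
    list(pixels = px, pixel_spacing_mm = RNifti::pixdim(img)[1],
         platform_id = platform_id, image_type = image_type,
         repeat_idx = as.integer(repeat_idx),
         applied_shift_px = c(dx = NA_real_, dy = NA_real_),
         seed_used = NA_integer_),
    class = "scan_image"
  )
}
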