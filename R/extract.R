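#' The 94-feature radiomics panel
#'
#' Returns the panel composition: 19 first-order, 24 GLCM, 14 GLDM, 16
#' GLRLM, 16 GLSZM and 5 NGTDM features (shape features are excluded by
#' design — the ROIs are fixed circles).
#' @return data frame with columns `feature_class`, `feature_name`
#' @export
feature_panel <- function() {
  zero <- discretize(matrix(c(1, 2, 3, 4), 2, 2), 1)
  rbind(
    data.frame(feature_class = "firstorder",
               feature_name = names(first_order_features(c(1, 2, 3, 4)))),
    data.frame(feature_class = "glcm", feature_name = names(glcm_features(zero))),
    data.frame(feature_class = "gldm", feature_name = names(gldm_features(zero))),
    data.frame(feature_class = "glrlm", feature_name = names(glrlm_features(zero))),
    data.frame(feature_class = "glszm", feature_name = names(glszm_features(zero))),
    data.frame(feature_class = "ngtdm", feature_name = names(ngtdm_features(zero)))
  )
}

#' Default extraction configuration
#' @param bin_width discretization bin width in HU
#' @param slice_thickness_mm slice thickness used for the voxel volume in
#'   Total Energy
#' @param glcm_distance,gldm_alpha,gldm_distance,ngtdm_distance texture
#'   parameters
#' @export
extraction_config <- function(bin_width = 25, slice_thickness_mm = 5,
                              glcm_distance = 1L, gldm_alpha = 0,
                              gldm_distance = 1L, ngtdm_distance = 1L) {
  list(bin_width = bin_width, slice_thickness_mm = slice_thickness_mm,
       glcm_distance = glcm_distance, gldm_alpha = gldm_alpha,
       gldm_distance = gldm_distance, ngtdm_distance = ngtdm_distance)
}

# All 94 features for one ROI grid (bounding-box matrix, NA outside ROI).
extract_panel_grid <- function(grid, config, voxel_volume_mm3) {
  d <- discretize(grid, config$bin_width)
  fo <- first_order_features(as.vector(grid), d, voxel_volume_mm3)
  vals <- c(fo,
            glcm_features(d, config$glcm_distance),
            gldm_features(d, config$gldm_alpha, config$gldm_distance),
            glrlm_features(d),
            glszm_features(d),
            ngtdm_features(d))
  cls <- rep(c("firstorder", "glcm", "gldm", "glrlm", "glszm", "ngtdm"),
             times = c(19L, 24L, 14L, 16L, 16L, 5L))
  data.frame(feature_class = cls, feature_name = names(vals),
             value = unname(vals), stringsAsFactors = FALSE)
}

#' Extract the full feature panel from one scan
#'
#' Computes the 94-feature panel for every ROI in `roi_set` on the original
#' image values: no resampling, filtering or normalization is applied before
#' fixed-bin-width discretization.
#'
#' @param image a `scan_image`
#' @param roi_set an `roi_set`
#' @param config an [extraction_config()] list
#' @param roi_ids ROIs to extract (default: all in `roi_set`)
#' @return data frame (FeatureTable rows) with columns `platform_id`,
#'   `image_type`, `repeat_idx`, `roi_id`, `feature_class`, `feature_name`,
#'   `value`; exactly 94 rows per ROI
#' @export
extract_all <- function(image, roi_set, config = extraction_config(),
                        roi_ids = roi_set$roi_id) {
  missing_ids <- setdiff(roi_ids, roi_set$roi_id)
  if (length(missing_ids))
    stop_radrobust("ROIs absent from roi_set: ",
                   paste(missing_ids, collapse = ", "))
  vv <- image$pixel_spacing_mm^2 * config$slice_thickness_mm
  per_roi <- lapply(roi_ids, function(id) {
    g <- roi_grid(image, roi_set, id)
    df <- extract_panel_grid(g, config, vv)
    df$roi_id <- id
    df
  })
  out <- do.call(rbind, per_roi)
  out$platform_id <- image$platform_id
  out$image_type <- image$image_type
  out$repeat_idx <- image$repeat_idx
  out[, c("platform_id", "image_type", "repeat_idx", "roi_id",
          "feature_class", "feature_name", "value")]
}

#' Simulate a study and extract its feature table in memory
#'
#' Convenience driver: for every (platform, image type, repeat) it simulates
#' the scan, estimates the rigid repositioning against a noiseless rendered
#' reference, places the registered ROIs and extracts the 94-feature panel.
#'
#' @inheritParams simulate_study
#' @param config an [extraction_config()]
#' @param register estimate and apply rigid registration (default TRUE);
#'   with FALSE the nominal ROI positions are used
#' @param reposition draw a random repositioning shift for repeats > 1
#'   (default TRUE); FALSE gives a noise-only test-retest design
#' @return list with `features` (the FeatureTable data frame), `scans`
#'   (per-scan metadata: seeds, applied and estimated shifts), `spec`,
#'   `platforms`, `seed`, `config`
#' @export
simulate_features <- function(spec = default_phantom_spec(),
                              platforms = default_platform_models(),
                              image_types = image_types_all(),
                              n_repeats = 2L, seed = 1L,
                              config = extraction_config(),
                              register = TRUE, reposition = TRUE) {
  refs <- lapply(stats::setNames(image_types, image_types),
                 function(ty) render_reference(spec, ty))
  feat <- list(); meta <- list()
  for (pl in platforms) for (ty in image_types) for (rp in seq_len(n_repeats)) {
    sseed <- derive_scan_seed(seed, pl$platform_id, ty, rp)
    sc <- simulate_scan(spec, pl, ty, repeat_idx = rp, seed = sseed,
                        shift_px = if (reposition) NULL else c(0, 0))
    if (register) {
      tr <- estimate_rigid(sc, refs[[ty]])
      roi <- make_roi_masks(spec, invert_rigid(tr))
      est <- c(dx = -tr$dx_px, dy = -tr$dy_px)
    } else {
      roi <- make_roi_masks(spec)
      est <- c(dx = 0, dy = 0)
    }
    feat[[length(feat) + 1L]] <- extract_all(sc, roi, config)
    meta[[length(meta) + 1L]] <- data.frame(
      platform_id = pl$platform_id, image_type = ty, repeat_idx = rp,
      seed = sseed,
      dx_applied = sc$applied_shift_px[["dx"]],
      dy_applied = sc$applied_shift_px[["dy"]],
      dx_estimated = est[["dx"]], dy_estimated = est[["dy"]])
  }
  list(features = do.call(rbind, feat), scans = do.call(rbind, meta),
       spec = spec, platforms = platforms, seed = seed, config = config)
}

#' Extract features for every scan listed in a study manifest
#'
#' Disk-based counterpart of [simulate_features()] for NIfTI images written
#' by [simulate_study()] (or real data following the same manifest schema).
#'
#' @param manifest data frame or path to a `manifest.csv` with columns
#'   `file_path`, `platform_id`, `image_type`, `repeat_idx`
#' @param dir directory that `file_path` entries are relative to
#' @param spec a `phantom_spec` providing the nominal ROI centres
#' @inheritParams simulate_features
#' @export
extract_study <- function(manifest, dir = ".", spec = default_phantom_spec(),
                          config = extraction_config(), register = TRUE) {
  if (is.character(manifest)) manifest <- utils::read.csv(manifest)
  refs <- lapply(stats::setNames(unique(manifest$image_type),
                                 unique(manifest$image_type)),
                 function(ty) render_reference(spec, ty))
  feat <- lapply(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, ]
    sc <- read_scan_nifti(file.path(dir, row$file_path), row$platform_id,
                          row$image_type, row$repeat_idx)
    roi <- if (register) {
      make_roi_masks(spec, invert_rigid(estimate_rigid(sc, refs[[row$image_type]])))
    } else make_roi_masks(spec)
    extract_all(sc, roi, config)
  })
  do.call(rbind, feat)
}
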