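#' Rigid (translation-only) registration between two scans
#'
#' Estimates the in-plane translation aligning `image` to `reference` by
#' maximizing the cross-correlation of the disk-thresholded (> -500 HU)
#' binary images, computed via FFT, with sub-pixel refinement by quadratic
#' interpolation of the correlation peak. Rotation is fixed at zero: between
#' table repositionings the phantom translates but cannot meaningfully
#' rotate at this level of abstraction.
#'
#' The returned translation is the correction to apply to `image`: if the
#' image content is displaced by `(+2, -1)` pixels relative to the
#' reference, the estimate is `(-2, +1)`.
#'
#' @param image,reference `scan_image` objects of identical shape/spacing
#' @return object of class `rigid_transform` with elements `dx_px`, `dy_px`
#'   (dx = column shift, dy = row shift)
#' @export
estimate_rigid <- function(image, reference) {
  if (!all(dim(image$pixels) == dim(reference$pixels)))
    stop_radrobust("image and reference have different shapes")
  a <- image$pixels > -500
  b <- reference$pixels > -500
  if (!any(a) || !any(b))
    stop_radrobust("empty foreground after thresholding",
                   class = "radrobust_degenerate_image")
  a <- a - mean(a); b <- b - mean(b)
  # ifft(fft(A) * Conj(fft(B))) peaks at the displacement of A relative to B
  cc <- Re(stats::fft(stats::fft(a) * Conj(stats::fft(b)), inverse = TRUE))
  n <- nrow(cc); m <- ncol(cc)
  pk <- arrayInd(which.max(cc), dim(cc))
  wrap <- function(i, N) ifelse(i - 1 > N / 2, i - 1 - N, i - 1)
  d_row <- wrap(pk[1], n); d_col <- wrap(pk[2], m)
  # quadratic sub-pixel interpolation along each axis
  subpix <- function(cm1, c0, cp1) {
    den <- cm1 - 2 * c0 + cp1
    if (abs(den) < .Machine$double.eps) return(0)
    delta <- 0.5 * (cm1 - cp1) / den
    max(-0.5, min(0.5, delta))
  }
  ri <- function(i, N) ((i - 1) %% N) + 1
  dr <- subpix(cc[ri(pk[1] - 1, n), pk[2]], cc[pk[1], pk[2]],
               cc[ri(pk[1] + 1, n), pk[2]])
  dc <- subpix(cc[pk[1], ri(pk[2] - 1, m)], cc[pk[1], pk[2]],
               cc[pk[1], ri(pk[2] + 1, m)])
  rigid_transform(dx_px = -(d_col + dc), dy_px = -(d_row + dr))
}

#' Construct / invert a translation-only rigid transform
#' @param dx_px,dy_px translation in pixels (dx = column, dy = row)
#' @export
rigid_transform <- function(dx_px = 0, dy_px = 0) {
  if (!is.finite(dx_px) || !is.finite(dy_px) ||
        abs(dx_px) > 20 || abs(dy_px) > 20)
    stop_radrobust("rigid transform out of sanity bounds (|d| <= 20 px)")
  structure(list(dx_px = dx_px, dy_px = dy_px), class = "rigid_transform")
}

#' @rdname rigid_transform
#' @param transform a `rigid_transform`
#' @export
invert_rigid <- function(transform) {
  rigid_transform(-transform$dx_px, -transform$dy_px)
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("RigidTransform: dx %+.3f px, dy %+.3f px (rotation fixed 0)\n",
              x$dx_px, x$dy_px))
  invisible(x)
}

# Common circular stencil: integer offsets whose pixel centres lie within
# diameter/2 of the (integer) ROI centre; ordered row-major.
roi_stencil <- function(diameter_px) {
  r <- diameter_px / 2
  ri <- as.integer(floor(r))
  g <- expand.grid(dc = -ri:ri, dr = -ri:ri)   # vary dc fastest within a row
  g <- g[g$dr^2 + g$dc^2 <= r^2, c("dr", "dc")]
  g <- g[order(g$dr, g$dc), ]
  as.matrix(g)
}

#' Circular ROI set centred on the phantom inserts
#'
#' Places one circular ROI of `diameter_px` pixels (default 26 px = 25.4 mm)
#' at the centre of each insert, displaced by `transform` (the scan's
#' estimated repositioning). A pixel belongs to a ROI iff its centre lies
#' within `diameter_px/2` of the ROI centre. All sixteen ROIs share one
#' integer stencil (the sub-pixel part of the common offset moves the stored
#' real-valued centres, not the mask), so every mask has the same pixel
#' count.
#'
#' @param spec a `phantom_spec`
#' @param transform a `rigid_transform` giving the displacement of the scan
#'   content relative to nominal geometry (i.e. the inverse of
#'   [estimate_rigid()]'s alignment correction)
#' @param diameter_px ROI diameter in pixels
#' @param matrix_size,fov_mm image geometry
#' @return object of class `roi_set`: integer mask centres (`centers_px`,
#'   row/col), real-valued centres (`centers_px_real`), the shared stencil
#'   and bookkeeping fields
#' @export
make_roi_masks <- function(spec, transform = rigid_transform(0, 0),
                           diameter_px = 26L, matrix_size = 512L,
                           fov_mm = 500) {
  s <- fov_mm / matrix_size
  half <- (matrix_size + 1) / 2
  nom_row <- spec$inserts$y_mm / s + half
  nom_col <- spec$inserts$x_mm / s + half
  off_row <- transform$dy_px; off_col <- transform$dx_px
  cen_row <- round(nom_row) + round(off_row)
  cen_col <- round(nom_col) + round(off_col)
  st <- roi_stencil(diameter_px)
  rmax <- max(abs(st[, 1]))
  if (any(cen_row - rmax < 1 | cen_row + rmax > matrix_size |
            cen_col - rmax < 1 | cen_col + rmax > matrix_size))
    stop_radrobust("ROI extends beyond image bounds",
                   class = "radrobust_bounds_error")
  structure(
    list(roi_id = spec$inserts$insert_id,
         centers_px = cbind(row = cen_row, col = cen_col),
         centers_px_real = cbind(row = nom_row + off_row,
                                 col = nom_col + off_col),
         diameter_px = as.integer(diameter_px), stencil = st,
         matrix_size = as.integer(matrix_size)),
    class = "roi_set"
  )
}

#' @export
print.roi_set <- function(x, ...) {
  cat(sprintf("ROISet: %d circular ROIs, diameter %d px, %d px each\n",
              length(x$roi_id), x$diameter_px, nrow(x$stencil)))
  invisible(x)
}

#' Dense logical mask for one ROI
#' @param roi_set an `roi_set`
#' @param roi_id ROI identifier (1-16)
#' @export
roi_mask <- function(roi_set, roi_id) {
  k <- match(roi_id, roi_set$roi_id)
  if (is.na(k)) stop_radrobust("unknown roi_id: ", roi_id)
  m <- matrix(FALSE, roi_set$matrix_size, roi_set$matrix_size)
  m[cbind(roi_set$centers_px[k, 1] + roi_set$stencil[, 1],
          roi_set$centers_px[k, 2] + roi_set$stencil[, 2])] <- TRUE
  m
}

#' Write the ROI set as a NIfTI label map (labels 1-16)
#' @inheritParams roi_mask
#' @param path output path
#' @param pixel_spacing_mm spacing stored in the header
#' @export
write_roi_labelmap <- function(roi_set, path, pixel_spacing_mm = 500 / 512) {
  lab <- matrix(0L, roi_set$matrix_size, roi_set$matrix_size)
  for (k in seq_along(roi_set$roi_id)) {
    lab[cbind(roi_set$centers_px[k, 1] + roi_set$stencil[, 1],
              roi_set$centers_px[k, 2] + roi_set$stencil[, 2])] <-
      roi_set$roi_id[k]
  }
  attr(lab, "pixdim") <- c(pixel_spacing_mm, pixel_spacing_mm)
  attr(lab, "pixunits") <- "mm"
  RNifti::writeNifti(RNifti::asNifti(lab, datatype = "int16"), path)
  invisible(path)
}

#' Extract ROI pixel values in row-major order
#'
#' Values are returned in row-major order of the masked pixels (by image
#' row, then column), which is the documented, stable ordering contract for
#' all downstream texture computations.
#' @param image a `scan_image`
#' @param roi_set an `roi_set`
#' @param roi_id ROI identifier
#' @export
extract_roi_values <- function(image, roi_set, roi_id) {
  k <- match(roi_id, roi_set$roi_id)
  if (is.na(k)) stop_radrobust("unknown roi_id: ", roi_id)
  if (!all(dim(image$pixels) == roi_set$matrix_size))
    stop_radrobust("image shape does not match ROI set")
  image$pixels[cbind(roi_set$centers_px[k, 1] + roi_set$stencil[, 1],
                     roi_set$centers_px[k, 2] + roi_set$stencil[, 2])]
}

#' Mean CT number (HU) within one ROI
#' @inheritParams extract_roi_values
#' @export
mean_ct_number <- function(image, roi_set, roi_id) {
  mean(extract_roi_values(image, roi_set, roi_id))
}

# Bounding-box grid of one ROI: matrix with NA outside the circular mask,
# used as input to the texture-matrix builders.
roi_grid <- function(image, roi_set, roi_id) {
  k <- match(roi_id, roi_set$roi_id)
  st <- roi_set$stencil
  rmax <- max(abs(st[, 1])); cmax <- max(abs(st[, 2]))
  g <- matrix(NA_real_, 2 * rmax + 1, 2 * cmax + 1)
  g[cbind(st[, 1] + rmax + 1, st[, 2] + cmax + 1)] <-
    extract_roi_values(image, roi_set, roi_id)
  g
}
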