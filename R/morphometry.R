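#' Bone volume fraction (BV/TV)
#'
#' @param bin A [binary_volume()] of segmented bone.
#' @param roi Optional [binary_volume()] region of interest (default: whole
#'   volume).
#' @return Fraction in `[0, 1]`: foreground voxels within the ROI divided by
#'   ROI voxels.
#' @export
bone_volume_fraction <- function(bin, roi = NULL) {
  stopifnot(inherits(bin, "binary_volume"))
  rdat <- roi_data(bin, roi)
  if (!any(rdat)) stop("ROI is empty")
  sum(bin$data & rdat) / sum(rdat)
}

roi_data <- function(bin, roi) {
  if (is.null(roi)) return(array(TRUE, dim(bin$data)))
  rdat <- if (inherits(roi, "binary_volume")) roi$data else roi
  stopifnot(identical(dim(rdat), dim(bin$data)))
  rdat
}

#' Specific bone surface (BS/BV)
#'
#' Triangulated iso-surface area of the foreground divided by foreground
#' volume, in 1/mm. The surface is extracted at the 0.5 iso-level by marching
#' tetrahedra; by default the binary field is first smoothed with a Gaussian
#' (`smooth_sigma` voxels) so edge crossings are linearly interpolated rather
#' than pinned to voxel midpoints, which removes most of the staircase-area
#' bias of raw binary extraction. No boundary padding is added: phases cut by
#' the volume faces are left open there, matching the in-ROI surface
#' convention.
#'
#' @inheritParams bone_volume_fraction
#' @param smooth_sigma Gaussian pre-smoothing in voxels (default 1; 0
#'   disables).
#' @return BS/BV in 1/mm.
#' @export
specific_bone_surface <- function(bin, roi = NULL, smooth_sigma = 1) {
  stopifnot(inherits(bin, "binary_volume"))
  rdat <- roi_data(bin, roi)
  fg <- bin$data & rdat
  if (!any(fg)) stop("no foreground voxels for surface estimation")
  field <- array(as.numeric(fg), dim(fg))
  if (smooth_sigma > 0) field <- blur3d(field, smooth_sigma)
  d <- dim(field)
  area_vox2 <- cpp_mt_area(as.numeric(field), d[1], d[2], d[3], 0.5)
  vs_mm <- bin$voxel_size_um / 1000
  (area_vox2 * vs_mm^2) / (sum(fg) * vs_mm^3)
}

#' Local thickness map (maximal inscribed spheres)
#'
#' Per-voxel thickness is the diameter of the largest sphere (disc in 2D)
#' that contains the voxel and fits entirely inside the selected phase
#' (distance-transform / sphere-fitting construction). Run on the foreground
#' it yields trabecular thickness; on the background, trabecular separation.
#' The phase is treated as continuing beyond the volume faces, so slabs or
#' rods cut by the boundary are not artificially thinned there.
#'
#' @param bin A [binary_volume()] or [section_image()] (2D mode; logical or
#'   0/1 data).
#' @param phase `"foreground"` or `"background"`.
#' @param roi Optional ROI; the mean is taken over phase voxels inside it.
#' @return List with `map` (thickness in voxels, `NA` outside the phase) and
#'   `mean_mm`.
#' @export
local_thickness <- function(bin, phase = c("foreground", "background"),
                            roi = NULL) {
  phase <- match.arg(phase)
  if (inherits(bin, "section_image")) {
    fg <- bin$data != 0
    d <- c(dim(fg), 1L)
    unit_mm <- bin$pixel_size_um / 1000
    dim(fg) <- d
  } else {
    stopifnot(inherits(bin, "binary_volume"))
    fg <- bin$data
    d <- dim(fg)
    unit_mm <- bin$voxel_size_um / 1000
  }
  ph <- if (phase == "foreground") fg else !fg
  if (!any(ph)) stop("selected phase is empty")
  th <- array(cpp_local_thickness(as.logical(ph), d[1], d[2], d[3]), d)
  sel <- ph
  if (!is.null(roi)) {
    rdat <- if (inherits(roi, "binary_volume")) roi$data else roi
    dim(rdat) <- d
    sel <- sel & rdat
    if (!any(sel)) stop("no phase voxels inside ROI")
  }
  list(map = th, mean_mm = mean(th[sel]) * unit_mm)
}

#' Trabecular number (Tb.N)
#'
#' Model-independent plate formula `Tb.N = (BV/TV) / Tb.Th`. Vendor software
#' may use other structural models; values are comparable, not identical.
#'
#' @param bv_tv Bone volume fraction in `[0, 1]`.
#' @param tb_th_mm Mean trabecular thickness in mm.
#' @return Trabecular number in 1/mm.
#' @export
trabecular_number <- function(bv_tv, tb_th_mm) {
  if (bv_tv == 0) return(0)
  if (tb_th_mm <= 0) stop("trabecular thickness must be positive")
  bv_tv / tb_th_mm
}

#' Box-counting fractal dimension
#'
#' Slope of `log(box count)` against `log(1/box size)` over dyadic box sizes
#' (1, 2, 4, ...) spanning at least three octaves, by least squares. Works on
#' 3D binary volumes (dimension in `(0, 3]`) and 2D sections (`(0, 2]`).
#'
#' @param bin A [binary_volume()] or [section_image()].
#' @return Scalar box-counting dimension.
#' @export
fractal_dimension <- function(bin) {
  if (inherits(bin, "section_image")) {
    fg <- bin$data != 0
  } else {
    stopifnot(inherits(bin, "binary_volume"))
    fg <- bin$data
  }
  if (!any(fg)) stop("no foreground voxels")
  d <- dim(fg)
  smax <- 2^floor(log2(min(d) / 2))
  sizes <- 2^(0:floor(log2(smax)))
  if (length(sizes) < 4)
    stop("volume too small for box counting over 3 octaves (need min dim >= 8)")
  idx <- which(fg, arr.ind = TRUE)
  counts <- vapply(sizes, function(s) {
    boxes <- floor((idx - 1) / s)
    nrow(unique(boxes))
  }, numeric(1))
  fit <- lm(log(counts) ~ log(1 / sizes))
  unname(coef(fit)[2])
}

#' Subchondral plate thickness
#'
#' Mean local thickness of the segmented bone restricted to the plate region
#' of interest, in mm.
#'
#' @param bin A [binary_volume()] of segmented bone.
#' @param plate_roi A [binary_volume()] marking the subchondral plate.
#' @return Mean plate thickness in mm.
#' @export
plate_thickness <- function(bin, plate_roi) {
  stopifnot(inherits(bin, "binary_volume"), inherits(plate_roi, "binary_volume"))
  if (!any(plate_roi$data)) stop("plate ROI is empty")
  fg <- binary_volume(bin$data & plate_roi$data, bin$voxel_size_um)
  if (!any(fg$data)) stop("no bone inside the plate ROI")
  local_thickness(fg, "foreground")$mean_mm
}

#' Conventional morphometry of one compartment
#'
#' Computes the re-implementable structural parameters in one call: BV/TV,
#' BS/BV, Tb.Th, Tb.Sp, Tb.N and fractal dimension. Structure model index,
#' connectivity (density), trabecular pattern factor and degree of anisotropy
#' are not computed here; the report schema reserves their names as optional
#' external inputs so a full conventional table can be assembled from mixed
#' sources.
#'
#' @inheritParams bone_volume_fraction
#' @return An object of class `morphometry_summary` (named list, units in
#'   field names).
#' @export
morphometry_summary <- function(bin, roi = NULL) {
  stopifnot(inherits(bin, "binary_volume"))
  rdat <- roi_data(bin, roi)
  bv_tv <- bone_volume_fraction(bin, roi)
  tb_th <- local_thickness(bin, "foreground", roi = rdat)$mean_mm
  tb_sp <- local_thickness(bin, "background", roi = rdat)$mean_mm
  structure(list(
    bv_tv = bv_tv,
    bs_bv_per_mm = specific_bone_surface(bin, roi),
    tb_th_mm = tb_th,
    tb_sp_mm = tb_sp,
    tb_n_per_mm = trabecular_number(bv_tv, tb_th),
    fractal_dim = fractal_dimension(bin)
  ), class = "morphometry_summary")
}

#' @export
print.morphometry_summary <- function(x, ...) {
  cat(sprintf(paste0("<morphometry_summary> BV/TV %.3f, BS/BV %.2f /mm, ",
                     "Tb.Th %.4f mm, Tb.Sp %.4f mm, Tb.N %.2f /mm, FD %.3f\n"),
              x$bv_tv, x$bs_bv_per_mm, x$tb_th_mm, x$tb_sp_mm,
              x$tb_n_per_mm, x$fractal_dim))
  invisible(x)
}
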