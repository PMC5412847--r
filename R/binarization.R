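#' Binarization parameters
#'
#' The segmentation recipe is two-stage: a fixed pre-threshold removes
#' marrow/background, then surviving voxels are kept only if they reach the
#' local midrange, i.e. the mean of the minimum and maximum intensity within a
#' window centred on the voxel.
#'
#' @param pre_threshold Fixed intensity threshold on the 8-bit scale
#'   (default 60). For 16-bit volumes the default is rescaled proportionally
#'   (`60/255` of full scale) unless a value is given explicitly.
#' @param window_radius_px Radius of the adaptive window in voxels (default 5).
#' @param window_shape `"ball"` (Euclidean radius, default) or `"cube"`
#'   (Chebyshev radius, an `(2r+1)^3` box).
#' @param slicewise Apply the adaptive window in 2D within each slice along
#'   the third axis instead of in 3D.
#' @return An object of class `binarization_params`.
#' @export
binarization_params <- function(pre_threshold = 60, window_radius_px = 5,
                                window_shape = c("ball", "cube"),
                                slicewise = FALSE) {
  window_shape <- match.arg(window_shape)
  if (!is.numeric(pre_threshold) || length(pre_threshold) != 1)
    stop("pre_threshold must be a scalar")
  if (window_radius_px < 1 || window_radius_px != round(window_radius_px))
    stop("window_radius_px must be a positive integer")
  explicit <- !missing(pre_threshold)
  structure(list(pre_threshold = pre_threshold,
                 window_radius_px = as.integer(window_radius_px),
                 window_shape = window_shape,
                 slicewise = isTRUE(slicewise),
                 pre_threshold_explicit = explicit),
            class = "binarization_params")
}

# Rescale the default 8-bit pre-threshold for deeper bit depths.
resolve_pre_threshold <- function(vol, params) {
  thr <- params$pre_threshold
  if (!isTRUE(params$pre_threshold_explicit) && max(vol$data) > 255)
    thr <- thr / 255 * 65535
  thr
}

#' Fixed pre-threshold mask
#'
#' A voxel passes when its intensity is greater than or equal to the
#' pre-threshold (boundary inclusive).
#'
#' @param vol A [gray_volume()].
#' @param params A [binarization_params()].
#' @return A [binary_volume()].
#' @export
pre_threshold_mask <- function(vol, params = binarization_params()) {
  stopifnot(inherits(vol, "gray_volume"), inherits(params, "binarization_params"))
  thr <- resolve_pre_threshold(vol, params)
  binary_volume(vol$data >= thr, vol$voxel_size_um)
}

#' Local midrange adaptive binarization
#'
#' Among voxels passing the pre-threshold, a voxel is foreground iff its
#' intensity reaches the local midrange `(min + max) / 2` computed over the
#' window centred on it (ties count as foreground, so constant volumes above
#' the pre-threshold stay solid). Windows are clipped at the volume boundary:
#' the extrema are taken over the intersection of window and volume.
#'
#' @inheritParams pre_threshold_mask
#' @return A [binary_volume()]; always a subset of [pre_threshold_mask()].
#' @export
adaptive_binarize <- function(vol, params = binarization_params()) {
  stopifnot(inherits(vol, "gray_volume"), inherits(params, "binarization_params"))
  pre <- pre_threshold_mask(vol, params)$data
  d <- dim(vol$data)
  r <- params$window_radius_px
  if (params$slicewise) {
    mid <- array(0, d)
    for (k in seq_len(d[3])) {
      mm <- cpp_minmax_filter(as.numeric(vol$data[, , k]), d[1], d[2], 1L,
                              r, params$window_shape == "ball")
      mid[, , k] <- (mm$min + mm$max) / 2
    }
  } else {
    mm <- cpp_minmax_filter(as.numeric(vol$data), d[1], d[2], d[3],
                            r, params$window_shape == "ball")
    mid <- array((mm$min + mm$max) / 2, d)
  }
  binary_volume(pre & (vol$data >= mid), vol$voxel_size_um)
}
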