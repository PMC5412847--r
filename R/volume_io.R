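#' Grayscale volume container
#'
#' A 3D scalar image with isotropic voxel-size metadata. The third array axis
#' is, by convention, the distal-proximal (longitudinal) axis everywhere in
#' this package; elevation angles are measured against it.
#'
#' @param data 3D numeric array of intensities (8/16-bit integers or floats).
#' @param voxel_size_um Positive scalar, isotropic voxel edge in micrometres.
#' @return An object of class `gray_volume` with elements `data` and
#'   `voxel_size_um`.
#' @examples
#' v <- gray_volume(array(0, c(4, 4, 4)), voxel_size_um = 27.8)
#' dim(v$data)
#' @export
gray_volume <- function(data, voxel_size_um) {
  data <- check_grid3d(data)
  if (!is.numeric(voxel_size_um) || length(voxel_size_um) != 1 ||
      !is.finite(voxel_size_um) || voxel_size_um <= 0)
    stop("voxel_size_um must be a positive finite scalar")
  if (!all(is.finite(data)))
    stop("volume intensities must be finite")
  structure(list(data = data, voxel_size_um = as.numeric(voxel_size_um)),
            class = "gray_volume")
}

#' Binary (bone/background) volume container
#'
#' @param data 3D logical array; `TRUE` marks bone/foreground.
#' @param voxel_size_um Positive scalar, micrometres.
#' @return An object of class `binary_volume`.
#' @export
binary_volume <- function(data, voxel_size_um) {
  data <- check_grid3d(data)
  storage.mode(data) <- "logical"
  if (anyNA(data)) stop("binary volume must not contain NA")
  structure(list(data = data, voxel_size_um = as.numeric(voxel_size_um)),
            class = "binary_volume")
}

#' 2D section image (histology mode)
#'
#' @param data 2D numeric or logical matrix.
#' @param pixel_size_um Positive scalar, micrometres.
#' @return An object of class `section_image`.
#' @export
section_image <- function(data, pixel_size_um) {
  if (!is.matrix(data) || any(dim(data) < 3))
    stop("section image must be a matrix with both dimensions >= 3")
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1 ||
      pixel_size_um <= 0)
    stop("pixel_size_um must be a positive scalar")
  structure(list(data = data, pixel_size_um = as.numeric(pixel_size_um)),
            class = "section_image")
}

check_grid3d <- function(data) {
  if (is.logical(data) || is.integer(data)) storage.mode(data) <- "double"
  if (!is.array(data) || length(dim(data)) != 3)
    stop("volume data must be a 3D array")
  if (any(dim(data) < 3))
    stop("all three volume dimensions must be >= 3")
  data
}

#' @export
print.gray_volume <- function(x, ...) {
  cat(sprintf("<gray_volume> %s voxels, %.4g um/voxel, range [%.4g, %.4g]\n",
              paste(dim(x$data), collapse = "x"), x$voxel_size_um,
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.binary_volume <- function(x, ...) {
  cat(sprintf("<binary_volume> %s voxels, %.4g um/voxel, %d foreground\n",
              paste(dim(x$data), collapse = "x"), x$voxel_size_um,
              sum(x$data)))
  invisible(x)
}

is_nifti_path <- function(path) grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)

#' Read a grayscale or mask volume
#'
#' Reads a multipage TIFF, a directory of numerically-sorted single-slice
#' TIFFs, or a NIfTI-1 file. TIFF pages become slices along the third
#' (distal-proximal) axis. For NIfTI input an isotropic voxel size present in
#' the header overrides the `voxel_size_um` argument.
#'
#' @param path File (multipage TIFF, `.nii`/`.nii.gz`) or directory of TIFF
#'   slices.
#' @param voxel_size_um Isotropic voxel size in micrometres; required for TIFF.
#' @param as_mask If `TRUE` return a [binary_volume()] (any nonzero voxel is
#'   foreground), following the 0/255 mask convention.
#' @return A [gray_volume()] or [binary_volume()].
#' @export
read_volume <- function(path, voxel_size_um = NULL, as_mask = FALSE) {
  if (is_nifti_path(path)) {
    img <- tryCatch(RNifti::readNifti(path),
                    error = function(e) stop("unreadable NIfTI file: ",
                                             conditionMessage(e)))
    pd <- RNifti::pixdim(img)[1:3]
    if (all(is.finite(pd)) && all(pd > 0)) {
      if (diff(range(pd)) > 1e-6 * max(pd))
        stop("anisotropic NIfTI voxels are not supported: pixdim = ",
             paste(signif(pd, 6), collapse = " x "))
      units <- tryCatch(RNifti::pixunits(img), error = function(e) "mm")
      scale <- if (any(units == "um")) 1 else 1000  # default NIfTI unit is mm
      voxel_size_um <- pd[1] * scale
    }
    arr <- array(as.numeric(img), dim = dim(img))
  } else {
    files <- if (dir.exists(path)) {
      fl <- list.files(path, pattern = "\\.tiff?$", full.names = TRUE,
                       ignore.case = TRUE)
      if (length(fl) == 0) stop("no TIFF slices found in directory: ", path)
      num <- suppressWarnings(as.numeric(gsub("\\D", "", basename(fl))))
      fl[order(num, basename(fl))]
    } else path
    pages <- tryCatch(
      unlist(lapply(files, tiff::readTIFF, all = TRUE, as.is = TRUE),
             recursive = FALSE),
      error = function(e) stop("unreadable TIFF: ", conditionMessage(e)))
    if (!is.list(pages)) pages <- list(pages)
    arr <- array(0, dim = c(dim(pages[[1]]), length(pages)))
    for (k in seq_along(pages)) arr[, , k] <- pages[[k]]
  }
  if (is.null(voxel_size_um))
    stop("voxel_size_um must be given (no voxel size in file header)")
  if (as_mask) binary_volume(arr != 0, voxel_size_um)
  else gray_volume(arr, voxel_size_um)
}

#' Write a volume to TIFF or NIfTI
#'
#' Grayscale integer data are written losslessly as 8- or 16-bit multipage
#' TIFF (bit depth chosen from the data range); non-integer data require NIfTI
#' output. Binary volumes are stored as 0/255 8-bit TIFF (or uint8-style
#' NIfTI), so that any nonzero voxel reads back as foreground.
#'
#' @param vol A [gray_volume()] or [binary_volume()].
#' @param path Output file ending in `.tif`/`.tiff` or `.nii`/`.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, c("gray_volume", "binary_volume")))
  data <- vol$data
  if (inherits(vol, "binary_volume")) data <- array(ifelse(data, 255, 0), dim(data))
  if (is_nifti_path(path)) {
    img <- RNifti::asNifti(data)
    RNifti::pixdim(img) <- rep(vol$voxel_size_um / 1000, 3)  # header in mm
    RNifti::writeNifti(img, path)
    return(invisible(path))
  }
  if (any(data != round(data)) || min(data) < 0)
    stop("TIFF output requires nonnegative integer intensities; use NIfTI for float data")
  bits <- if (max(data) <= 255) 8L else 16L
  if (max(data) > 65535) stop("intensities exceed 16-bit TIFF range")
  denom <- 2^bits - 1
  pages <- lapply(seq_len(dim(data)[3]), function(k) data[, , k] / denom)
  ok <- tryCatch(tiff::writeTIFF(pages, path, bits.per.sample = bits),
                 error = function(e) stop("cannot write TIFF: ",
                                          conditionMessage(e)))
  invisible(path)
}

#' Crop a volume and mask to the mask's bounding box
#'
#' Mirrors the separation of the manually-segmented subchondral plate from
#' trabecular bone: the analysis region is supplied as a mask and the volume
#' is restricted to its bounding box, with the cropped mask retained so that
#' downstream operations count only in-mask voxels.
#'
#' @param vol A [gray_volume()].
#' @param mask A [binary_volume()] of the same shape.
#' @return A list with elements `volume` (cropped [gray_volume()]) and `mask`
#'   (cropped [binary_volume()]).
#' @export
extract_roi <- function(vol, mask) {
  stopifnot(inherits(vol, "gray_volume"), inherits(mask, "binary_volume"))
  if (!identical(dim(vol$data), dim(mask$data)))
    stop("volume and mask shapes differ")
  if (!any(mask$data))
    stop("mask is empty: region contains no trabecular bone")
  rng <- lapply(1:3, function(ax) {
    hit <- which(apply(mask$data, ax, any))
    range(hit)
  })
  idx <- lapply(rng, function(r) r[1]:r[2])
  vdat <- vol$data[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  mdat <- mask$data[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  if (any(dim(vdat) < 3))
    stop("mask bounding box smaller than 3 voxels along an axis")
  list(volume = gray_volume(vdat, vol$voxel_size_um),
       mask = binary_volume(mdat, vol$voxel_size_um))
}
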