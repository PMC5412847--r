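#' Pattern validity rules for orientation analysis
#'
#' Patterns without a consistent orientation are excluded before elevation is
#' computed: too few markers (< `min_markers`), too many markers
#' (> `max_markers`), or — with the centroid rule on — marker sets whose mean
#' distance to their own centroid exceeds the mean distance of the non-marker
#' positions to that centroid (dispersed, ring-like marker sets).
#'
#' @param min_markers Minimum marker count (default 3).
#' @param max_markers Maximum marker count (default 24).
#' @param centroid_rule Apply the centroid-dispersion rule (default `TRUE`).
#' @return An object of class `pattern_validity`.
#' @export
pattern_validity <- function(min_markers = 3, max_markers = 24,
                             centroid_rule = TRUE) {
  if (min_markers < 1 || max_markers >= 26 || min_markers > max_markers)
    stop("require 0 < min_markers <= max_markers < 26")
  structure(list(min_markers = as.integer(min_markers),
                 max_markers = as.integer(max_markers),
                 centroid_rule = isTRUE(centroid_rule)),
            class = "pattern_validity")
}

marker_bits <- function(code) {
  code <- as.integer(round(code))
  which(bitwAnd(bitwShiftR(code, 0:25), 1L) == 1L)
}

#' Does an LBP code have a consistent orientation?
#'
#' @param code Integer LBP code.
#' @param nbhd A [spherical_neighborhood()].
#' @param rules A [pattern_validity()].
#' @return Logical scalar.
#' @export
is_valid_pattern <- function(code, nbhd = spherical_neighborhood(),
                             rules = pattern_validity()) {
  mk <- marker_bits(code)
  n <- length(mk)
  if (n < rules$min_markers || n > rules$max_markers) return(FALSE)
  if (rules$centroid_rule && n < 26) {
    pos <- nbhd$directions * nbhd$radius_vox
    cen <- colMeans(pos[mk, , drop = FALSE])
    dmk <- sqrt(rowSums(sweep(pos[mk, , drop = FALSE], 2, cen)^2))
    dnm <- sqrt(rowSums(sweep(pos[-mk, , drop = FALSE], 2, cen)^2))
    if (mean(dmk) > mean(dnm)) return(FALSE)
  }
  TRUE
}

#' Elevation angle of a pattern's principal axis
#'
#' The marker positions on the sampling sphere are centred on their centroid
#' and the first principal axis is taken from the eigen-decomposition of their
#' 3x3 covariance. The elevation is the angle of that axis against the
#' transverse plane, measured along the distal-proximal (third) axis:
#' `asin(|axis . z|)` in degrees, so 90 deg is longitudinal and 0 deg is
#' transverse. The azimuth is ignored. When the two leading eigenvalues tie
#' (relative gap below 1e-9) there is no unique principal axis and `NA` is
#' returned; [elevation_field()] treats such voxels as invalid.
#'
#' @inheritParams is_valid_pattern
#' @return Elevation in degrees in `[0, 90]`, or `NA` for a degenerate axis.
#' @export
pattern_elevation <- function(code, nbhd = spherical_neighborhood(),
                              rules = pattern_validity()) {
  if (!is_valid_pattern(code, nbhd, rules))
    stop("pattern is not valid for orientation analysis; filter with is_valid_pattern()")
  elevation_of_code(code, nbhd)
}

elevation_of_code <- function(code, nbhd) {
  mk <- marker_bits(code)
  pos <- nbhd$directions[mk, , drop = FALSE] * nbhd$radius_vox
  x <- sweep(pos, 2, colMeans(pos))
  ee <- eigen(crossprod(x) / nrow(x), symmetric = TRUE)
  if (ee$values[1] - ee$values[2] <= 1e-9 * max(ee$values[1], .Machine$double.eps))
    return(NA_real_)
  v <- ee$vectors[, 1]
  asin(min(1, abs(v[3]))) * 180 / pi
}

#' Per-voxel elevation field
#'
#' Computes the LBP code of every masked voxel and maps it to the elevation
#' of its principal axis. Invalid patterns (validity rules, degenerate axis)
#' and unmasked voxels carry the `NA` sentinel. Elevation is computed once per
#' distinct code and looked up.
#'
#' @inheritParams lbp_histogram
#' @param rules A [pattern_validity()].
#' @param bin_width_deg Width of the elevation histogram bins in degrees
#'   (default 5, giving 18 bins over `[0, 90]`).
#' @return An object of class `elevation_field`: `angles` (3D array, degrees
#'   or `NA`), `bin_width_deg`, `n_evaluated` (masked voxel count).
#' @export
elevation_field <- function(vol, mask, nbhd = spherical_neighborhood(),
                            rules = pattern_validity(), bin_width_deg = 5) {
  mdat <- if (inherits(mask, "binary_volume")) mask$data else mask
  stopifnot(identical(dim(mdat), dim(vol$data)))
  if (!any(mdat)) stop("mask is empty: no voxels to analyse")
  fl <- lbp_fields(vol, nbhd)
  if (any(mdat & !fl$interior))
    stop("mask includes boundary voxels; restrict it to the interior")
  codes <- fl$codes[mdat]
  uc <- unique(codes)
  elev <- vapply(uc, function(cd) {
    if (!is_valid_pattern(cd, nbhd, rules)) NA_real_
    else elevation_of_code(cd, nbhd)
  }, numeric(1))
  angles <- array(NA_real_, dim(vol$data))
  angles[mdat] <- elev[match(codes, uc)]
  structure(list(angles = angles, bin_width_deg = bin_width_deg,
                 n_evaluated = sum(mdat)),
            class = "elevation_field")
}

#' @export
print.elevation_field <- function(x, ...) {
  nv <- sum(!is.na(x$angles))
  cat(sprintf("<elevation_field> %d valid voxels of %d evaluated, %g deg bins\n",
              nv, x$n_evaluated, x$bin_width_deg))
  invisible(x)
}

n_elevation_bins <- function(bin_width_deg) as.integer(ceiling(90 / bin_width_deg))

# Bin index in 1..n_bins; 90 deg closes the last bin.
elevation_bin_index <- function(angles, bin_width_deg) {
  nb <- n_elevation_bins(bin_width_deg)
  pmin(floor(angles / bin_width_deg) + 1L, nb)
}

#' Mean, entropy and validity of an elevation field
#'
#' @param field An [elevation_field()].
#' @return An object of class `orientation_summary`: `mean_elevation_deg`,
#'   `elevation_entropy_bits` (Shannon entropy of the binned elevation
#'   distribution), `valid_fraction`.
#' @export
elevation_summary <- function(field) {
  stopifnot(inherits(field, "elevation_field"))
  a <- field$angles[!is.na(field$angles)]
  if (length(a) == 0) stop("no valid voxels in the elevation field")
  bins <- elevation_bin_index(a, field$bin_width_deg)
  p <- tabulate(bins, nbins = n_elevation_bins(field$bin_width_deg))
  p <- p[p > 0] / length(a)
  structure(list(mean_elevation_deg = mean(a),
                 elevation_entropy_bits = -sum(p * log2(p)),
                 valid_fraction = length(a) / field$n_evaluated),
            class = "orientation_summary")
}

# The 13 positive lattice offsets of the 26-neighborhood (both orders of each
# pair are counted, which symmetrizes the matrix).
half_offsets_26 <- function() {
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  off[off[, 3] > 0 | (off[, 3] == 0 & (off[, 2] > 0 |
      (off[, 2] == 0 & off[, 1] > 0))), , drop = FALSE]
}

#' Angle-level co-occurrence matrix (ALCM)
#'
#' Element `(i, j)` accumulates the occurrences of a voxel with binned
#' elevation `i` having a voxel with binned elevation `j` in its vicinity
#' (within one voxel-size radius, i.e. the 26-adjacent voxels; a 6-adjacency
#' option is provided). Both orders of every pair are counted, making the
#' matrix symmetric, and it is normalized to sum to 1.
#'
#' @param field An [elevation_field()].
#' @param adjacency `"26"` (default) or `"6"` face-only.
#' @return An object of class `alc_matrix`: the normalized matrix with
#'   attributes `bin_width_deg` and `n_pairs` (ordered pair count).
#' @export
compute_alcm <- function(field, adjacency = c("26", "6")) {
  stopifnot(inherits(field, "elevation_field"))
  adjacency <- match.arg(adjacency)
  nb <- n_elevation_bins(field$bin_width_deg)
  bins <- array(NA_integer_, dim(field$angles))
  ok <- !is.na(field$angles)
  bins[ok] <- elevation_bin_index(field$angles[ok], field$bin_width_deg)
  d <- dim(bins)
  offs <- half_offsets_26()
  if (adjacency == "6") offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  counts <- matrix(0, nb, nb)
  for (k in seq_len(nrow(offs))) {
    o <- offs[k, ]
    sa <- lapply(1:3, function(ax) max(1, 1 - o[ax]):min(d[ax], d[ax] - o[ax]))
    a <- bins[sa[[1]], sa[[2]], sa[[3]], drop = FALSE]
    b <- bins[sa[[1]] + o[1], sa[[2]] + o[2], sa[[3]] + o[3], drop = FALSE]
    keep <- !is.na(a) & !is.na(b)
    if (!any(keep)) next
    tab <- tabulate((a[keep] - 1L) * nb + b[keep], nbins = nb * nb)
    counts <- counts + matrix(tab, nb, nb, byrow = TRUE)
  }
  counts <- counts + t(counts)   # count both orders of each pair
  n_pairs <- sum(counts)
  if (n_pairs == 0) stop("no adjacent pairs of valid voxels for the ALCM")
  structure(counts / n_pairs, class = "alc_matrix",
            bin_width_deg = field$bin_width_deg, n_pairs = n_pairs)
}

#' Homogeneity of elevation
#'
#' `H = sum_{i,j} ALCM(i,j) / (1 + |i - j|)` over bin indices. Equals 1 when
#' every co-occurring pair of neighboring voxels falls in the same elevation
#' bin (continuous orientation) and decreases as neighboring elevations
#' diverge.
#'
#' @param alcm An [compute_alcm()] result (normalized).
#' @return Scalar in `(0, 1]`.
#' @export
homogeneity_of_elevation <- function(alcm) {
  stopifnot(inherits(alcm, "alc_matrix"))
  nb <- nrow(alcm)
  idx <- abs(outer(seq_len(nb), seq_len(nb), "-"))
  sum(unclass(alcm) / (1 + idx))
}

#' Full orientation summary of a volume
#'
#' Convenience wrapper: elevation field, its summary, the ALCM and the
#' homogeneity of elevation in one call.
#'
#' @inheritParams elevation_field
#' @return An `orientation_summary` with `homogeneity` added.
#' @export
orientation_summary <- function(vol, mask, nbhd = spherical_neighborhood(),
                                rules = pattern_validity(), bin_width_deg = 5) {
  field <- elevation_field(vol, mask, nbhd, rules, bin_width_deg)
  s <- elevation_summary(field)
  s$homogeneity <- homogeneity_of_elevation(compute_alcm(field))
  s
}

#' @export
print.orientation_summary <- function(x, ...) {
  cat(sprintf(paste0("<orientation_summary> mean elevation %.2f deg, entropy ",
                     "%.4f bits, valid fraction %.3f"),
              x$mean_elevation_deg, x$elevation_entropy_bits, x$valid_fraction))
  if (!is.null(x$homogeneity)) cat(sprintf(", homogeneity %.4f", x$homogeneity))
  cat("\n")
  invisible(x)
}
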