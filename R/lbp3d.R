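#' Spherical 26-neighbor sampling geometry
#'
#' The 26 directions are the normalized offsets of the 3x3x3 neighborhood
#' (centre excluded), enumerated in a fixed lexicographic order over
#' `(dz, dy, dx)`. Neighbors are placed on a sphere of radius `radius_vox`
#' around the studied voxel and sampled by trilinear interpolation, so the six
#' axial neighbors fall on lattice points only when the radius is an integer.
#'
#' @param radius_vox Sphere radius in voxels (default 1).
#' @return An object of class `spherical_neighborhood` with elements
#'   `radius_vox`, `directions` (26 x 3 matrix of unit vectors, columns x,y,z)
#'   and `offsets` (26 x 3 integer matrix of the generating lattice offsets).
#' @export
spherical_neighborhood <- function(radius_vox = 1.0) {
  if (!is.numeric(radius_vox) || length(radius_vox) != 1 || radius_vox <= 0)
    stop("radius_vox must be a positive scalar")
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  off <- off[order(off[, "dz"], off[, "dy"], off[, "dx"]), ]
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  dirs <- off / sqrt(rowSums(off^2))
  dimnames(dirs) <- list(NULL, c("x", "y", "z"))
  dimnames(off) <- list(NULL, c("x", "y", "z"))
  structure(list(radius_vox = as.numeric(radius_vox),
                 directions = unname(dirs),
                 offsets = unname(off)),
            class = "spherical_neighborhood")
}

# Relative tolerance for >= comparisons between interpolated neighbor values
# and the centre value: trilinear weights only sum to 1 up to rounding, and
# without slack a constant volume would not reliably yield the all-marker code.
LBP_TOL <- 1e-9

#' Trilinear samples of the 26 spherical neighbors of one voxel
#'
#' @param vol A [gray_volume()].
#' @param centre Integer voxel index `c(x, y, z)` (1-based), at least
#'   `ceiling(radius)` voxels from every face.
#' @param nbhd A [spherical_neighborhood()].
#' @return Numeric vector of 26 interpolated gray values in direction order.
#' @export
sample_neighbors <- function(vol, centre, nbhd = spherical_neighborhood()) {
  stopifnot(inherits(vol, "gray_volume"), length(centre) == 3)
  d <- dim(vol$data)
  m <- ceiling(nbhd$radius_vox)
  if (any(centre < 1 + m) || any(centre > d - m))
    stop("centre voxel closer than ceiling(radius) to a volume face")
  pos <- sweep(nbhd$directions * nbhd$radius_vox, 2, centre, "+")
  vapply(seq_len(nrow(pos)), function(i) trilinear_at(vol$data, pos[i, ]),
         numeric(1))
}

trilinear_at <- function(arr, p) {
  b <- floor(p); f <- p - b
  out <- 0
  for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
    w <- (if (cx) f[1] else 1 - f[1]) *
         (if (cy) f[2] else 1 - f[2]) *
         (if (cz) f[3] else 1 - f[3])
    if (w == 0) next
    out <- out + w * arr[b[1] + cx, b[2] + cy, b[3] + cz]
  }
  out
}

#' LBP code from centre and neighbor values
#'
#' Bit `i` (value `2^(i-1)`) is set when neighbor `i` has a gray value equal
#' to or higher than the centre; such neighbors are the pattern's "markers".
#'
#' @param centre_value Scalar gray value of the studied voxel.
#' @param neighbor_values Numeric vector of 26 sampled neighbor values.
#' @return Integer code in `[0, 2^26 - 1]`.
#' @export
compute_code <- function(centre_value, neighbor_values) {
  stopifnot(length(neighbor_values) == 26)
  bits <- neighbor_values >= centre_value - LBP_TOL * (1 + abs(centre_value))
  as.integer(sum(2^(which(bits) - 1)))
}

# Vectorized interior LBP evaluation. Returns, over the full volume grid,
# the code (NA at boundary), the maximum sampled neighbor value (for the
# eligibility rule), and the interior indicator. Each direction's trilinear
# stencil has constant fractional weights, so sampling is 26 shifted
# weighted sums of subarrays.
lbp_fields <- function(vol, nbhd = spherical_neighborhood()) {
  arr <- vol$data
  d <- dim(arr)
  m <- ceiling(nbhd$radius_vox)
  if (any(d < 2 * m + 1)) stop("volume too small for this neighborhood radius")
  i1 <- rep(1 + m, 3); i2 <- d - m
  ctr <- arr[i1[1]:i2[1], i1[2]:i2[2], i1[3]:i2[3], drop = FALSE]
  codes <- array(0, dim(ctr))
  nbmax <- array(-Inf, dim(ctr))
  thr <- ctr - LBP_TOL * (1 + abs(ctr))
  pos <- nbhd$directions * nbhd$radius_vox
  for (i in seq_len(26)) {
    b <- floor(pos[i, ]); f <- pos[i, ] - b
    s <- array(0, dim(ctr))
    for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
      w <- (if (cx) f[1] else 1 - f[1]) *
           (if (cy) f[2] else 1 - f[2]) *
           (if (cz) f[3] else 1 - f[3])
      if (w == 0) next
      o <- b + c(cx, cy, cz)
      s <- s + w * arr[(i1[1] + o[1]):(i2[1] + o[1]),
                       (i1[2] + o[2]):(i2[2] + o[2]),
                       (i1[3] + o[3]):(i2[3] + o[3]), drop = FALSE]
    }
    codes <- codes + 2^(i - 1) * (s >= thr)
    nbmax <- pmax(nbmax, s)
  }
  full_codes <- array(NA_real_, d)
  full_max <- array(NA_real_, d)
  interior <- array(FALSE, d)
  full_codes[i1[1]:i2[1], i1[2]:i2[2], i1[3]:i2[3]] <- codes
  full_max[i1[1]:i2[1], i1[2]:i2[2], i1[3]:i2[3]] <- nbmax
  interior[i1[1]:i2[1], i1[2]:i2[2], i1[3]:i2[3]] <- TRUE
  list(codes = full_codes, nbmax = full_max, interior = interior)
}

#' Eligibility mask for LBP analysis
#'
#' A voxel enters the analysis only when at least one of its 26 sampled
#' neighbors has a gray value strictly above a fixed threshold, so the
#' histogram captures bone rather than empty marrow space. Voxels within
#' `ceiling(radius)` of a face are never eligible (no extrapolation).
#'
#' @inheritParams sample_neighbors
#' @param fixed_threshold Intensity threshold; by default the binarization
#'   pre-threshold (60 on the 8-bit scale).
#' @return A [binary_volume()].
#' @export
eligibility_mask <- function(vol, nbhd = spherical_neighborhood(),
                             fixed_threshold = 60) {
  fl <- lbp_fields(vol, nbhd)
  elig <- fl$interior & !is.na(fl$nbmax) & (fl$nbmax > fixed_threshold)
  elig[is.na(elig)] <- FALSE
  binary_volume(array(elig, dim(vol$data)), vol$voxel_size_um)
}

#' Histogram of volumetric LBP codes
#'
#' Counts the LBP code of every masked voxel. The mask must be restricted to
#' interior voxels (intersect any region-of-interest mask with
#' [eligibility_mask()] first).
#'
#' @inheritParams sample_neighbors
#' @param mask A [binary_volume()] (or logical array) of voxels to count.
#' @return An object of class `pattern_histogram`: list with `counts` (named
#'   integer vector, names are decimal codes), `total`, and `proportions`.
#' @export
lbp_histogram <- function(vol, mask, nbhd = spherical_neighborhood()) {
  mdat <- if (inherits(mask, "binary_volume")) mask$data else mask
  stopifnot(identical(dim(mdat), dim(vol$data)))
  if (!any(mdat)) stop("mask is empty: no voxels to analyse")
  fl <- lbp_fields(vol, nbhd)
  if (any(mdat & !fl$interior))
    stop("mask includes boundary voxels; restrict it to the interior")
  codes <- fl$codes[mdat]
  tab <- table(codes)
  counts <- as.integer(tab)
  names(counts) <- names(tab)
  pattern_histogram(counts)
}

#' Construct a pattern histogram from code counts
#'
#' @param counts Named nonnegative integer vector; names are decimal LBP codes.
#' @return An object of class `pattern_histogram`.
#' @export
pattern_histogram <- function(counts) {
  counts <- counts[counts > 0]
  if (length(counts) == 0) stop("histogram has no counts")
  if (is.null(names(counts))) stop("counts must be named by LBP code")
  code_num <- as.numeric(names(counts))
  if (anyNA(code_num) || any(code_num < 0) || any(code_num >= 2^26))
    stop("histogram keys must be valid 26-bit LBP codes")
  o <- order(code_num)
  counts <- counts[o]
  total <- sum(counts)
  structure(list(counts = counts, total = total,
                 proportions = counts / total),
            class = "pattern_histogram")
}

#' @export
print.pattern_histogram <- function(x, ...) {
  cat(sprintf("<pattern_histogram> %d distinct patterns over %d voxels\n",
              length(x$counts), x$total))
  invisible(x)
}

#' Shannon entropy of the pattern distribution
#'
#' `E = -sum_i P_i log2(P_i)` over the proportions of each distinct LBP code;
#' a volume containing a single local pattern has entropy zero, and higher
#' values reflect more heterogeneous local structure.
#'
#' @param hist A [pattern_histogram()].
#' @return Entropy in bits (scalar, `>= 0`).
#' @export
pattern_entropy <- function(hist) {
  stopifnot(inherits(hist, "pattern_histogram"))
  p <- hist$proportions
  p <- p[p > 0]
  -sum(p * log2(p))
}

# Number of set bits in each 26-bit code.
popcount26 <- function(codes) {
  codes <- as.integer(round(codes))
  out <- integer(length(codes))
  for (k in 0:25) out <- out + bitwAnd(bitwShiftR(codes, k), 1L)
  out
}

#' Summary statistics of an LBP histogram
#'
#' @param hist A [pattern_histogram()].
#' @return An object of class `lbp_summary`: `entropy_bits`,
#'   `n_distinct_patterns`, and `mean_marker_count` (count-weighted mean
#'   number of set bits, in `[0, 26]`).
#' @export
lbp_summary <- function(hist) {
  stopifnot(inherits(hist, "pattern_histogram"))
  codes <- as.numeric(names(hist$counts))
  pc <- popcount26(codes)
  structure(list(entropy_bits = pattern_entropy(hist),
                 n_distinct_patterns = length(hist$counts),
                 mean_marker_count = sum(pc * hist$counts) / hist$total),
            class = "lbp_summary")
}

#' @export
print.lbp_summary <- function(x, ...) {
  cat(sprintf(paste0("<lbp_summary> entropy %.4f bits, %d distinct patterns, ",
                     "mean markers %.3f\n"),
              x$entropy_bits, x$n_distinct_patterns, x$mean_marker_count))
  invisible(x)
}
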