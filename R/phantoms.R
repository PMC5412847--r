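#' Parametric phantom specification
#'
#' Describes a synthetic gray-level volume with analytic ground truth, used to
#' validate every analysis operation. Kinds:
#' \describe{
#'   \item{`rod_lattice`}{Parallel cylindrical rods on a square lattice in the
#'     plane perpendicular to the rod axis; the axis has the requested
#'     elevation against the transverse plane (azimuth 0). Truth: elevation,
#'     `bv_tv = pi r^2 / spacing^2`, rod diameter, spacing.}
#'   \item{`plate_stack`}{Parallel plates of given thickness stacked with the
#'     given spacing along the third axis. Truth: thickness,
#'     `bv_tv = thickness / spacing`.}
#'   \item{`sphere_pack`}{Spheres on a simple cubic lattice. Truth:
#'     `bv_tv = (4/3) pi r^3 / spacing^3`.}
#'   \item{`ramp`}{Strictly increasing intensity along the third axis; every
#'     interior voxel carries the same LBP code, so pattern entropy is 0.}
#'   \item{`two_phase_noise`}{Smoothed seeded Gaussian noise thresholded at a
#'     quantile, giving an irregular two-intensity structure with the
#'     requested volume fraction.}
#' }
#'
#' @param kind Phantom kind (see above).
#' @param size_vox Integer triple of volume dimensions.
#' @param elevation_deg Rod axis elevation in degrees, `[0, 90]` (rod_lattice).
#' @param element_radius_vox Rod/sphere radius in voxels.
#' @param thickness_vox Plate thickness in voxels (plate_stack).
#' @param spacing_vox Lattice spacing in voxels.
#' @param volume_fraction Target foreground fraction (two_phase_noise).
#' @param fg_intensity,bg_intensity Foreground/background gray levels
#'   (defaults 200/40 on the 8-bit scale; `fg > bg` required).
#' @param blur_sigma_vox Gaussian blur applied after rasterization (voxels).
#' @param noise_sd Additive Gaussian noise standard deviation.
#' @param voxel_size_um Voxel size recorded in the output (default 27.8).
#' @param seed Integer seed controlling all randomness.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(kind = c("rod_lattice", "plate_stack", "sphere_pack",
                                  "ramp", "two_phase_noise"),
                         size_vox = c(64, 64, 64), elevation_deg = 90,
                         element_radius_vox = 3, thickness_vox = 4,
                         spacing_vox = 12, volume_fraction = 0.3,
                         fg_intensity = 200, bg_intensity = 40,
                         blur_sigma_vox = 0, noise_sd = 0,
                         voxel_size_um = 27.8, seed = 1L) {
  kind <- match.arg(kind)
  if (length(size_vox) != 3 || any(size_vox < 3))
    stop("size_vox must be a triple with all dimensions >= 3")
  if (fg_intensity <= bg_intensity) stop("fg_intensity must exceed bg_intensity")
  if (elevation_deg < 0 || elevation_deg > 90)
    stop("elevation_deg must lie in [0, 90]")
  if (blur_sigma_vox < 0 || noise_sd < 0)
    stop("blur and noise parameters must be nonnegative")
  if (kind %in% c("rod_lattice", "sphere_pack") &&
      spacing_vox <= 2 * element_radius_vox)
    stop("spacing_vox must exceed 2 * element_radius_vox (non-overlap)")
  if (kind == "plate_stack" && spacing_vox <= thickness_vox)
    stop("spacing_vox must exceed thickness_vox")
  structure(list(kind = kind, size_vox = as.integer(size_vox),
                 elevation_deg = elevation_deg,
                 element_radius_vox = element_radius_vox,
                 thickness_vox = thickness_vox, spacing_vox = spacing_vox,
                 volume_fraction = volume_fraction,
                 fg_intensity = fg_intensity, bg_intensity = bg_intensity,
                 blur_sigma_vox = blur_sigma_vox, noise_sd = noise_sd,
                 voxel_size_um = voxel_size_um, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate a phantom volume with its ground truth
#'
#' Rasterizes the structure by distance thresholding in continuous space (so
#' analytic volume fractions hold to discretization error), then applies the
#' requested blur and noise via [degrade()]. Deterministic for a fixed seed.
#'
#' @param spec A [phantom_spec()].
#' @return List with `volume` (a [gray_volume()]) and `truth` (named list of
#'   the analytic quantities applicable to the kind).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$size_vox
  # voxel-centre coordinates, 0-based
  x <- array(rep(seq_len(d[1]) - 1, times = d[2] * d[3]), d)
  y <- array(rep(rep(seq_len(d[2]) - 1, each = d[1]), times = d[3]), d)
  z <- array(rep(seq_len(d[3]) - 1, each = d[1] * d[2]), d)
  fg <- NULL
  truth <- list(kind = spec$kind)
  if (spec$kind == "rod_lattice") {
    el <- spec$elevation_deg * pi / 180
    axis <- c(cos(el), 0, sin(el))            # azimuth 0: rods in the x-z plane
    e1 <- c(-sin(el), 0, cos(el))             # orthonormal complement
    e2 <- c(0, 1, 0)
    s <- spec$spacing_vox; r <- spec$element_radius_vox
    u1 <- x * e1[1] + y * e1[2] + z * e1[3]
    u2 <- x * e2[1] + y * e2[2] + z * e2[3]
    # rotate the perpendicular lattice so rod centres are incommensurate with
    # the voxel grid: sub-voxel phases then average out and voxel counts track
    # the analytic cross-section area (rod direction is unaffected)
    phi <- 0.48
    v1 <- cos(phi) * u1 + sin(phi) * u2
    v2 <- -sin(phi) * u1 + cos(phi) * u2
    r1 <- v1 - s * round(v1 / s)
    r2 <- v2 - s * round(v2 / s)
    fg <- (r1^2 + r2^2) <= r^2
    truth$elevation_deg <- spec$elevation_deg
    truth$bv_tv <- pi * r^2 / s^2
    truth$rod_diameter_mm <- 2 * r * spec$voxel_size_um / 1000
    truth$spacing_mm <- s * spec$voxel_size_um / 1000
    truth$tb_n_per_mm <- truth$bv_tv / truth$rod_diameter_mm
  } else if (spec$kind == "plate_stack") {
    s <- spec$spacing_vox; t <- spec$thickness_vox
    w <- z - s * round(z / s)
    fg <- abs(w) <= t / 2
    truth$thickness_mm <- t * spec$voxel_size_um / 1000
    truth$bv_tv <- t / s
  } else if (spec$kind == "sphere_pack") {
    s <- spec$spacing_vox; r <- spec$element_radius_vox
    rx <- x - s * round(x / s)
    ry <- y - s * round(y / s)
    rz <- z - s * round(z / s)
    fg <- (rx^2 + ry^2 + rz^2) <= r^2
    truth$bv_tv <- (4 / 3) * pi * r^3 / s^3
    truth$sphere_diameter_mm <- 2 * r * spec$voxel_size_um / 1000
  } else if (spec$kind == "ramp") {
    arr <- spec$bg_intensity +
      (spec$fg_intensity - spec$bg_intensity) * z / max(1, d[3] - 1)
    truth$n_distinct_patterns <- 1L
    truth$pattern_entropy_bits <- 0
    vol <- gray_volume(arr, spec$voxel_size_um)
    vol <- degrade(vol, spec$blur_sigma_vox, spec$noise_sd, spec$seed)
    return(list(volume = vol, truth = truth))
  } else if (spec$kind == "two_phase_noise") {
    noise <- with_local_seed(spec$seed, array(rnorm(prod(d)), d))
    smooth <- blur3d(noise, 2)
    cut <- quantile(smooth, 1 - spec$volume_fraction)
    fg <- smooth >= cut
    truth$bv_tv <- mean(fg)
  }
  arr <- array(ifelse(fg, spec$fg_intensity, spec$bg_intensity), d)
  vol <- gray_volume(arr, spec$voxel_size_um)
  vol <- degrade(vol, spec$blur_sigma_vox, spec$noise_sd, spec$seed + 1L)
  list(volume = vol, truth = truth)
}

#' Degrade a volume with blur and noise
#'
#' Gaussian blur followed by additive Gaussian noise, clipped to the input
#' volume's intensity range. Reproducible for a fixed seed; the global RNG
#' state is left untouched.
#'
#' @param vol A [gray_volume()].
#' @param blur_sigma_vox Blur standard deviation in voxels (0 = none).
#' @param noise_sd Noise standard deviation in intensity units (0 = none).
#' @param seed Integer seed for the noise.
#' @return A [gray_volume()].
#' @export
degrade <- function(vol, blur_sigma_vox = 0, noise_sd = 0, seed = 1L) {
  stopifnot(inherits(vol, "gray_volume"))
  if (blur_sigma_vox < 0 || noise_sd < 0)
    stop("blur and noise parameters must be nonnegative")
  arr <- vol$data
  rng <- range(arr)
  if (blur_sigma_vox > 0) arr <- blur3d(arr, blur_sigma_vox)
  if (noise_sd > 0) {
    noise <- with_local_seed(seed, array(rnorm(length(arr), sd = noise_sd),
                                         dim(arr)))
    arr <- arr + noise
    arr <- pmin(pmax(arr, rng[1]), rng[2])
    dim(arr) <- dim(vol$data)
  }
  gray_volume(arr, vol$voxel_size_um)
}
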