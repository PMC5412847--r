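# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (per-voxel loops, closed forms) so they share no code
# with the implementation they check.

# trilinear interpolation via explicit corner weights
oracle_trilinear <- function(arr, p) {
  b <- floor(p)
  f <- p - b
  acc <- 0
  for (i in 0:1) for (j in 0:1) for (k in 0:1) {
    w <- prod(ifelse(c(i, j, k) == 1, f, 1 - f))
    if (w == 0) next  # zero-weight corners may sit outside the grid
    acc <- acc + w * arr[b[1] + i, b[2] + j, b[3] + k]
  }
  acc
}

# per-voxel LBP codes by direct looping
oracle_codes <- function(vol, nbhd) {
  arr <- vol$data
  d <- dim(arr)
  m <- ceiling(nbhd$radius_vox)
  out <- array(NA_real_, d)
  for (z in (1 + m):(d[3] - m))
    for (y in (1 + m):(d[2] - m))
      for (x in (1 + m):(d[1] - m)) {
        ctr <- arr[x, y, z]
        code <- 0
        for (i in 1:26) {
          p <- c(x, y, z) + nbhd$radius_vox * nbhd$directions[i, ]
          if (oracle_trilinear(arr, p) >= ctr) code <- code + 2^(i - 1)
        }
        out[x, y, z] <- code
      }
  out
}

oracle_histogram <- function(vol, mask, nbhd) {
  codes <- oracle_codes(vol, nbhd)
  table(codes[mask])
}

# principal axis via SVD of the centred marker positions (different
# decomposition than the implementation's eigen route); NA when the two
# leading covariance eigenvalues tie (no unique axis)
oracle_elevation <- function(code, nbhd, check_tie = FALSE) {
  bits <- which(bitwAnd(bitwShiftR(as.integer(code), 0:25), 1L) == 1L)
  pos <- nbhd$directions[bits, , drop = FALSE] * nbhd$radius_vox
  xc <- sweep(pos, 2, colMeans(pos))
  sv <- svd(xc)
  ev <- sv$d^2 / nrow(xc)
  if (check_tie &&
      ev[1] - ev[2] <= 1e-9 * max(ev[1], .Machine$double.eps))
    return(NA_real_)
  asin(min(1, abs(sv$v[3, 1]))) * 180 / pi
}

# ALCM by direct enumeration of all ordered 26-adjacent pairs
oracle_alcm <- function(bins, n_bins) {
  d <- dim(bins)
  counts <- matrix(0, n_bins, n_bins)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  for (z in 1:d[3]) for (y in 1:d[2]) for (x in 1:d[1]) {
    a <- bins[x, y, z]
    if (is.na(a)) next
    for (k in 1:26) {
      q <- c(x, y, z) + offs[k, ]
      if (any(q < 1) || any(q > d)) next
      b <- bins[q[1], q[2], q[3]]
      if (is.na(b)) next
      counts[a, b] <- counts[a, b] + 1
    }
  }
  counts / sum(counts)
}

# windowed min/max by per-voxel search
oracle_minmax_mid <- function(arr, radius, shape) {
  d <- dim(arr)
  mid <- array(NA_real_, d)
  for (z in 1:d[3]) for (y in 1:d[2]) for (x in 1:d[1]) {
    xs <- max(1, x - radius):min(d[1], x + radius)
    ys <- max(1, y - radius):min(d[2], y + radius)
    zs <- max(1, z - radius):min(d[3], z + radius)
    vals <- c()
    for (zz in zs) for (yy in ys) for (xx in xs) {
      if (shape == "ball" &&
          (xx - x)^2 + (yy - y)^2 + (zz - z)^2 > radius^2) next
      vals <- c(vals, arr[xx, yy, zz])
    }
    mid[x, y, z] <- (min(vals) + max(vals)) / 2
  }
  mid
}

# solid ball mask centred on a voxel centre
ball_mask <- function(n, r, centre = rep((n + 1) %/% 2, 3)) {
  co <- as.matrix(expand.grid(1:n, 1:n, 1:n))
  d2 <- (co[, 1] - centre[1])^2 + (co[, 2] - centre[2])^2 +
        (co[, 3] - centre[3])^2
  array(d2 <= r^2, c(n, n, n))
}

# Menger-sponge-like set sampled on an n^3 grid: a cell is kept unless, at
# any of `level` triadic scales, at least two of its three base-3 digits
# equal 1 (the classic generator, resampled so dyadic box sizes span enough
# octaves)
menger_mask <- function(n = 64, level = 3) {
  co <- as.matrix(expand.grid(0:(n - 1), 0:(n - 1), 0:(n - 1)))
  u <- floor(co * (3^level) / n)
  keep <- rep(TRUE, nrow(co))
  for (l in 0:(level - 1)) {
    dig <- (u %/% 3^l) %% 3
    keep <- keep & rowSums(dig == 1) < 2
  }
  array(keep, rep(n, 3))
}

# two rod-lattice phantoms interleaved in `k` alternating slabs along x,
# mixing longitudinal and transverse orientation
mixed_rod_volume <- function(k, size = 64, seed = 1) {
  a <- generate_phantom(phantom_spec("rod_lattice", size_vox = rep(size, 3),
        elevation_deg = 90, element_radius_vox = 3, spacing_vox = 12,
        blur_sigma_vox = 1, seed = seed))$volume
  b <- generate_phantom(phantom_spec("rod_lattice", size_vox = rep(size, 3),
        elevation_deg = 0, element_radius_vox = 3, spacing_vox = 12,
        blur_sigma_vox = 1, seed = seed))$volume
  if (k > 1) {
    slab <- ceiling(size / k)
    band <- ((seq_len(size) - 1) %/% slab) %% 2 == 1
    a$data[band, , ] <- b$data[band, , ]
  }
  a
}

random_volume <- function(n, seed, lo = 0, hi = 255) {
  set.seed(seed)
  gray_volume(array(runif(n^3, lo, hi), rep(n, 3)), 27.8)
}
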