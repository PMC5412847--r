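test_that("the spherical neighborhood has 26 unique unit directions", {
  nb <- spherical_neighborhood(1.0)
  expect_equal(nrow(nb$directions), 26)
  expect_equal(nrow(unique(nb$directions)), 26)
  expect_equal(sqrt(rowSums(nb$directions^2)), rep(1, 26), tolerance = 1e-12)
  # six axial neighbors sit on exact lattice offsets at radius 1
  axial <- rowSums(nb$offsets != 0) == 1
  expect_equal(sum(axial), 6)
  expect_equal(nb$directions[axial, ], nb$offsets[axial, ] * 1.0)
  # radius scales every direction's reach
  nb2 <- spherical_neighborhood(1.7)
  expect_equal(sqrt(rowSums((nb2$directions * nb2$radius_vox)^2)),
               rep(1.7, 26), tolerance = 1e-12)
  expect_error(spherical_neighborhood(0), "positive")
})

test_that("neighbor sampling is trilinear", {
  # exact on a linear field
  d <- c(7, 7, 7)
  ramp <- gray_volume(array(rep(1:7, each = 49), d), 27.8)
  nb <- spherical_neighborhood(1)
  s <- sample_neighbors(ramp, c(4, 4, 4), nb)
  zplus <- which(nb$offsets[, 3] == 1 & rowSums(nb$offsets != 0) == 1)
  expect_equal(s[zplus], ramp$data[4, 4, 5])
  # constant volume samples are constant
  const <- gray_volume(array(3.7, d), 27.8)
  expect_equal(sample_neighbors(const, c(4, 4, 4), nb), rep(3.7, 26))
  # random volume matches the 8-corner weighted-sum oracle on diagonals
  vol <- random_volume(7, seed = 31)
  s <- sample_neighbors(vol, c(4, 4, 4), nb)
  for (i in which(rowSums(nb$offsets != 0) == 3)) {
    p <- c(4, 4, 4) + nb$directions[i, ]
    expect_equal(s[i], oracle_trilinear(vol$data, p), tolerance = 1e-12)
  }
  expect_error(sample_neighbors(vol, c(1, 4, 4), nb), "face")
})

test_that("codes mark neighbors with equal or higher gray value", {
  expect_identical(compute_code(10, rep(5, 26)), 0L)
  expect_identical(compute_code(10, rep(10, 26)), as.integer(2^26 - 1))
  expect_identical(compute_code(10, rep(15, 26)), as.integer(2^26 - 1))
  nbv <- rep(0, 26); nbv[c(1, 3, 26)] <- 99
  expect_identical(compute_code(50, nbv), as.integer(2^0 + 2^2 + 2^25))
})

test_that("eligibility requires a neighbor above the fixed threshold", {
  nb <- spherical_neighborhood(1)
  dark <- gray_volume(array(50, rep(8, 3)), 27.8)
  expect_false(any(eligibility_mask(dark, nb, 60)$data))
  expect_false(any(eligibility_mask(dark, nb, 50)$data))  # strict >
  # everything interior is eligible at threshold -Inf
  el <- eligibility_mask(dark, nb, -Inf)$data
  expect_true(all(el[2:7, 2:7, 2:7]))
  expect_equal(sum(el), 6^3)  # boundary voxels never eligible
  # a single bright voxel: eligibility equals the brute-force neighborhood
  # check (interpolated diagonal samples dilute the spike below threshold)
  arr <- array(0, rep(9, 3)); arr[5, 5, 5] <- 200
  bright <- gray_volume(arr, 27.8)
  got <- eligibility_mask(bright, nb, 60)$data
  want <- array(FALSE, rep(9, 3))
  for (z in 2:8) for (y in 2:8) for (x in 2:8) {
    smax <- max(vapply(1:26, function(i)
      oracle_trilinear(arr, c(x, y, z) + nb$directions[i, ]), numeric(1)))
    want[x, y, z] <- smax > 60
  }
  expect_identical(got, want)
  expect_true(any(want))
})

test_that("a strictly increasing ramp has exactly one interior pattern", {
  d <- c(10, 10, 10)
  ramp <- gray_volume(array(rep(seq(0, 250, length.out = 10), each = 100), d),
                      27.8)
  nb <- spherical_neighborhood(1)
  mask <- array(FALSE, d); mask[2:9, 2:9, 2:9] <- TRUE
  h <- lbp_histogram(ramp, mask, nb)
  expect_equal(length(h$counts), 1)
  expect_equal(h$total, 8^3)
  expect_equal(pattern_entropy(h), 0)
})

test_that("an alternating field yields two codes at equal counts", {
  d <- c(6, 6, 6)
  co <- as.matrix(expand.grid(1:6, 1:6, 1:6))
  par <- (rowSums(co) %% 2 == 0)
  arr <- array(ifelse(par, 200, 100), d)
  vol <- gray_volume(arr, 27.8)
  mask <- array(FALSE, d); mask[2:5, 2:5, 2:5] <- TRUE
  h <- lbp_histogram(vol, mask, spherical_neighborhood(1))
  expect_equal(length(h$counts), 2)
  expect_equal(unname(as.integer(h$counts)), c(32L, 32L))
  expect_equal(pattern_entropy(h), 1.0)
})

test_that("histograms match the naive per-voxel loop oracle", {
  vol <- random_volume(12, seed = 32)
  nb <- spherical_neighborhood(1)
  mask <- array(FALSE, rep(12, 3)); mask[2:11, 2:11, 2:11] <- TRUE
  h <- lbp_histogram(vol, mask, nb)
  want <- oracle_histogram(vol, mask, nb)
  expect_equal(h$total, sum(mask))
  expect_identical(sort(as.numeric(names(h$counts))),
                   sort(as.numeric(names(want))))
  want_sorted <- want[order(as.numeric(names(want)))]
  expect_equal(unname(as.integer(h$counts)), unname(as.integer(want_sorted)))
})

test_that("histogram masks must exclude boundary voxels", {
  vol <- random_volume(8, seed = 33)
  mask <- array(TRUE, rep(8, 3))
  expect_error(lbp_histogram(vol, mask, spherical_neighborhood(1)), "boundary")
  expect_error(lbp_histogram(vol, array(FALSE, rep(8, 3)),
                             spherical_neighborhood(1)), "empty")
})

test_that("entropy has its closed-form values", {
  h2 <- pattern_histogram(c("3" = 5L, "9" = 5L))
  expect_equal(pattern_entropy(h2), 1.0)
  h3 <- pattern_histogram(c("1" = 2L, "2" = 1L, "4" = 1L))
  expect_equal(pattern_entropy(h3), 1.5)
  expect_equal(pattern_entropy(pattern_histogram(c("77" = 4L))), 0)
})

test_that("summary statistics match a direct weighted-popcount computation", {
  all_ones <- as.character(2^26 - 1)
  h <- pattern_histogram(stats::setNames(c(3L, 3L), c("0", all_ones)))
  s <- lbp_summary(h)
  expect_equal(s$mean_marker_count, 13)
  expect_equal(s$n_distinct_patterns, 2)
  h1 <- pattern_histogram(stats::setNames(1L, all_ones))
  expect_equal(lbp_summary(h1)$mean_marker_count, 26)
  # random histogram vs direct summation
  set.seed(34)
  codes <- sample(0:(2^26 - 1), 40)
  counts <- sample(1:9, 40, replace = TRUE)
  h <- pattern_histogram(stats::setNames(as.integer(counts),
                                         as.character(codes)))
  popc <- vapply(codes, function(cd)
    sum(bitwAnd(bitwShiftR(as.integer(cd), 0:25), 1L)), numeric(1))
  o <- order(codes)
  expect_equal(lbp_summary(h)$mean_marker_count,
               sum(popc[o] * counts[o]) / sum(counts))
  expect_lte(lbp_summary(h)$entropy_bits, log2(40))
})

test_that("codes are invariant under affine gray-level maps", {
  vol <- random_volume(10, seed = 35)
  nb <- spherical_neighborhood(1)
  mask <- array(FALSE, rep(10, 3)); mask[2:9, 2:9, 2:9] <- TRUE
  h0 <- lbp_histogram(vol, mask, nb)
  for (ab in list(c(2, 10), c(0.5, -3), c(7, 0))) {
    mapped <- gray_volume(ab[1] * vol$data + ab[2], vol$voxel_size_um)
    h1 <- lbp_histogram(mapped, mask, nb)
    expect_identical(names(h0$counts), names(h1$counts))
    expect_identical(as.integer(h0$counts), as.integer(h1$counts))
  }
})
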