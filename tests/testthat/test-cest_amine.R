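offsets <- default_cest_offsets()

test_that("zspectrum_series validates its offset scheme", {
  Z <- matrix(1, 4, length(offsets))
  expect_s3_class(spectra_series(Z, offsets), "zspectrum_series")
  expect_error(spectra_series(Z[, 1:10], offsets[1:10]), ">= 3 offsets")
  bad <- offsets; bad[2] <- bad[1]
  expect_error(spectra_series(Z, bad), "increasing")
})

test_that("z-spectrum clustering separates distinct field offsets", {
  # two voxel populations: DeltaB0 = 0 vs +0.2 ppm
  Z <- rbind(
    t(replicate(30, two_pool_spectrum(offsets, 0.02, b0 = 0))),
    t(replicate(30, two_pool_spectrum(offsets, 0.02, b0 = 0.2))))
  Z <- Z + matrix(rnorm(length(Z), 0, 0.002), nrow(Z))
  s <- spectra_series(Z, offsets)
  mask <- binary_mask(array(TRUE, c(60, 1, 1)))
  cl <- cluster_zspectra(s, mask, n_clusters = 2, seed = 5)
  lab <- cl$labels
  # perfect separation: one label per population
  expect_length(unique(lab[1:30]), 1)
  expect_length(unique(lab[31:60]), 1)
  expect_false(lab[1] == lab[31])

  # determinism under a fixed seed
  cl2 <- cluster_zspectra(s, mask, n_clusters = 2, seed = 5)
  expect_identical(cl$labels, cl2$labels)

  # homogeneous spectra collapse to one effective cluster
  Zh <- t(replicate(20, two_pool_spectrum(offsets, 0.02)))
  sh <- spectra_series(Zh, offsets)
  mh <- binary_mask(array(TRUE, c(20, 1, 1)))
  clh <- suppressWarnings(cluster_zspectra(sh, mh, n_clusters = 3, seed = 1))
  cent_spread <- max(apply(clh$centroids, 2, function(x) diff(range(x))))
  expect_lt(cent_spread, 1e-6)

  expect_error(cluster_zspectra(sh, first_n_mask(2, c(20, 1, 1)),
                                n_clusters = 4), "fewer")
})

test_that("estimate_b0 recovers Lorentzian centers and applies the 0.3 ppm rule", {
  mk_cl <- function(b0s) {
    Z <- t(sapply(b0s, function(b) two_pool_spectrum(offsets, 0.02, b0 = b)))
    s <- spectra_series(Z, offsets)
    mask <- binary_mask(array(TRUE, c(length(b0s), 1, 1)))
    cluster_zspectra(s, mask, n_clusters = length(unique(b0s)), seed = 3)
  }
  cl <- mk_cl(rep(c(0.10, 0, 0.35), each = 10))
  b0 <- estimate_b0(cl)
  lab_of <- function(i) b0$delta_b0[i]
  expect_equal(lab_of(1), 0.10, tolerance = 0.01)
  expect_equal(lab_of(11), 0, tolerance = 0.01)
  expect_equal(lab_of(21), 0.35, tolerance = 0.01)
  # only the 0.35 ppm population violates the exclusion threshold
  expect_true(all(b0$flagged[21:30]))
  expect_false(any(b0$flagged[1:20]))
})

test_that("B0 correction restores a shifted Lorentzian and is idempotent", {
  shift <- 0.1
  Z <- t(replicate(8, two_pool_spectrum(offsets, 0.025, b0 = shift)))
  s <- spectra_series(Z, offsets)
  mask <- binary_mask(array(TRUE, c(8, 1, 1)))
  cl <- suppressWarnings(cluster_zspectra(s, mask, n_clusters = 2, seed = 2))
  b0 <- estimate_b0(cl)
  expect_equal(unique(round(b0$delta_b0, 3)), shift, tolerance = 0.01)

  corr <- correct_b0(s, b0)
  truth <- two_pool_spectrum(offsets, 0.025, b0 = 0)
  inner <- abs(offsets) <= 3.2  # clamped edge offsets excluded
  expect_lt(max(abs(corr$signal[1, inner] - truth[inner])), 0.005)

  # re-estimation after correction: residual |DeltaB0| < 0.01 ppm
  cl2 <- suppressWarnings(cluster_zspectra(corr, mask, n_clusters = 2,
                                           seed = 2))
  b02 <- estimate_b0(cl2)
  expect_lt(max(abs(b02$delta_b0)), 0.01)

  # zero-shift correction is the identity
  b0_zero <- b0
  b0_zero$delta_b0[] <- 0
  same <- correct_b0(s, b0_zero)
  expect_equal(same$signal, s$signal)
})

test_that("MTR_asym matches the analytic two-pool value and is 0 for symmetric spectra", {
  # symmetric spectrum (water only)
  Zs <- t(replicate(5, two_pool_spectrum(offsets, 0)))
  expect_equal(as.numeric(compute_mtr_asym(spectra_series(Zs, offsets))$data),
               rep(0, 5), tolerance = 1e-12)

  # two-pool oracle: direct numerical evaluation of the band average
  lor <- function(d, g) (g / 2)^2 / ((g / 2)^2 + d^2)
  band <- offsets[offsets >= 2.8 & offsets <= 3.2]
  for (a in c(0.01, 0.024, 0.05)) {
    oracle <- 100 * mean(
      two_pool_spectrum(-band, a) - two_pool_spectrum(band, a))
    Z <- t(replicate(3, two_pool_spectrum(offsets, a)))
    got <- as.numeric(compute_mtr_asym(spectra_series(Z, offsets))$data)
    expect_equal(got, rep(oracle, 3), tolerance = 1e-8)
    # equivalently 100 * a * band-mean of the amine asymmetry factor
    expect_equal(oracle,
                 100 * a * mean(lor(band - 3, 1) - lor(-band - 3, 1)),
                 tolerance = 1e-12)
  }

  # monotone in the amine amplitude
  vals <- sapply(seq(0, 0.06, by = 0.01), function(a) {
    Z <- matrix(two_pool_spectrum(offsets, a), 1)
    as.numeric(compute_mtr_asym(spectra_series(Z, offsets))$data)
  })
  expect_true(all(diff(vals) > 0))

  # nonpositive s0 masks the voxel
  s <- spectra_series(t(replicate(2, two_pool_spectrum(offsets, 0.02))),
                      offsets)
  s$s0[2] <- 0
  out <- compute_mtr_asym(s)
  expect_true(is.na(out$data[2, 1, 1]))
})

test_that("lesion-level CEST exclusion follows the flagged-fraction rule", {
  nv <- 20
  cl_labels <- rep(1:2, each = 10)
  b0 <- structure(list(
    delta_b0 = c(rep(0.05, 10), rep(0.4, 10)),
    flagged = c(rep(FALSE, 10), rep(TRUE, 10)),
    voxels = 1:nv, threshold = 0.3), class = "b0_map")
  tumor_ok <- first_n_mask(8, c(20, 1, 1))        # all unflagged
  arr <- array(FALSE, c(20, 1, 1)); arr[7:14] <- TRUE
  tumor_mixed <- binary_mask(arr)                  # half flagged
  expect_true(cest_lesion_valid(b0, tumor_ok))
  expect_false(cest_lesion_valid(b0, tumor_mixed))
  expect_true(cest_lesion_valid(b0, tumor_mixed, max_flagged_frac = 0.6))
})
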