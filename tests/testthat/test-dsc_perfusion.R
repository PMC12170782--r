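# Shared small DSC fixture: gamma-variate reference on a 60 s axis.
dsc_time <- seq(0, 59, by = 1)
dsc_xbar <- gbmphen:::gamma_variate(dsc_time, t0 = 12, alpha = 3, tp = 4,
                                    peak = 6)

test_that("signal_to_delta_r2star matches its closed form", {
  te <- 0.035
  nvox <- 3
  nt <- 20
  sig <- matrix(100, nvox, nt)
  # voxel 2: one frame at S = S_b * exp(-te * 10) -> DeltaR2* = 10 there
  sig[2, 15] <- 100 * exp(-te * 10)
  # voxel 3: nonpositive baseline -> masked
  sig[3, ] <- -1
  s <- dsc_series(sig, tr = 1, te = te, baseline_idx = 1:5,
                  voxels = 1:3, dim3 = c(3, 1, 1))
  d <- signal_to_delta_r2star(s)
  expect_equal(max(abs(d$curves[1, ])), 0)
  expect_equal(d$curves[2, 15], 10, tolerance = 1e-12)
  expect_true(all(is.na(d$curves[3, ])))
  expect_error(dsc_series(sig, tr = 1, te = -1, voxels = 1:3,
                          dim3 = c(3, 1, 1)), "te")
})

test_that("baseline detection finds the pre-bolus window", {
  sig <- 100 - 40 * dsc_xbar / max(dsc_xbar) +
    stats::rnorm(length(dsc_time), 0, 0.3)
  bl <- detect_baseline(sig)
  # bolus arrives at t0 = 12 s; detected baseline must end just before
  expect_gte(length(bl), 8)
  expect_lte(length(bl), 14)
})

test_that("leakage convolution at kep = 0 is the running integral", {
  conv0 <- leakage_convolution(dsc_xbar, dsc_time, 0)
  oracle <- pracma::cumtrapz(dsc_time, dsc_xbar)
  expect_equal(conv0, as.numeric(oracle), tolerance = 1e-10)
})

test_that("bidirectional leakage fit recovers forward-model parameters", {
  # leak-free identity
  f0 <- fit_bidirectional_leakage(1.0 * dsc_xbar, dsc_xbar, dsc_time)
  expect_equal(f0$k1, 1, tolerance = 1e-8)
  expect_equal(f0$k2, 0, tolerance = 1e-8)
  expect_equal(f0$rss, 0, tolerance = 1e-10)

  # forward model with kep on the grid: exact recovery
  grid <- default_kep_grid()
  kep_true <- grid[8]
  curve <- 0.8 * dsc_xbar -
    0.05 * leakage_convolution(dsc_xbar, dsc_time, kep_true)
  f1 <- fit_bidirectional_leakage(curve, dsc_xbar, dsc_time, grid)
  expect_equal(f1$k1, 0.8, tolerance = 1e-6)
  expect_equal(f1$k2, 0.05, tolerance = 1e-6)
  expect_equal(f1$kep, kep_true)
  expect_lt(f1$rss, 1e-12)

  # off-grid kep: k1 still within 5 percent
  curve2 <- 0.8 * dsc_xbar -
    0.05 * leakage_convolution(dsc_xbar, dsc_time, 0.013)
  f2 <- fit_bidirectional_leakage(curve2, dsc_xbar, dsc_time, grid)
  expect_lt(abs(f2$k1 - 0.8) / 0.8, 0.05)

  expect_error(fit_bidirectional_leakage(curve, rep(0, length(dsc_time)),
                                         dsc_time), "reference")
})

test_that("kep_grid = {0} agrees with direct normal-equation least squares", {
  set.seed(31)
  curve <- 1.2 * dsc_xbar -
    0.03 * leakage_convolution(dsc_xbar, dsc_time, 0) +
    rnorm(length(dsc_time), 0, 0.05)
  fit <- fit_bidirectional_leakage(curve, dsc_xbar, dsc_time, kep_grid = 0)
  # oracle: unidirectional (Boxerman-style) two-parameter LSQ via lm
  X2 <- -leakage_convolution(dsc_xbar, dsc_time, 0)
  oracle <- stats::lm(curve ~ 0 + dsc_xbar + X2)
  expect_equal(fit$k1, unname(coef(oracle)[1]), tolerance = 1e-8)
  expect_equal(fit$k2, unname(coef(oracle)[2]), tolerance = 1e-8)
  expect_equal(fit$rss, sum(resid(oracle)^2), tolerance = 1e-8)
})

test_that("compute_rcbv normalizes the brain median to one", {
  # homogeneous brain: every voxel the same bolus -> rCBV identically 1
  nv <- 50
  te <- 0.035
  meas <- matrix(rep(dsc_xbar, each = nv), nv)
  sig <- 600 * exp(-te * meas)
  s <- dsc_series(sig, tr = 1, te = te, baseline_idx = 1:10,
                  voxels = 1:nv, dim3 = c(nv, 1, 1))
  brain <- binary_mask(array(TRUE, c(nv, 1, 1)), kind = "brain")
  rcbv <- compute_rcbv(s, brain)
  expect_equal(as.numeric(rcbv$data), rep(1, nv), tolerance = 1e-6)

  # a double-amplitude voxel reads ~2 relative to background
  meas2 <- meas
  meas2[7, ] <- 2 * dsc_xbar
  sig2 <- 600 * exp(-te * meas2)
  s2 <- dsc_series(sig2, tr = 1, te = te, baseline_idx = 1:10,
                   voxels = 1:nv, dim3 = c(nv, 1, 1))
  rcbv2 <- compute_rcbv(s2, brain)
  expect_equal(rcbv2$data[7, 1, 1], 2, tolerance = 0.02)
  expect_equal(median(as.numeric(rcbv2$data), na.rm = TRUE), 1,
               tolerance = 1e-9)
})

test_that("leak-free voxels keep their uncorrected integral", {
  nv <- 30
  te <- 0.035
  set.seed(32)
  k1v <- runif(nv, 0.5, 2)
  meas <- tcrossprod(k1v, dsc_xbar)
  sig <- 600 * exp(-te * meas)
  s <- dsc_series(sig, tr = 1, te = te, baseline_idx = 1:10,
                  voxels = 1:nv, dim3 = c(nv, 1, 1))
  brain <- binary_mask(array(TRUE, c(nv, 1, 1)), kind = "brain")
  rcbv <- compute_rcbv(s, brain)
  # corrected map proportional to k1 truth, normalized to its median
  expect_equal(as.numeric(rcbv$data), k1v / median(k1v), tolerance = 1e-4)
})

test_that("vectorized leakage fit recovers k1 within 5% at SNR 50", {
  set.seed(33)
  nv <- 1000
  grid <- default_kep_grid()
  k1v <- runif(nv, 0.6, 1.8)
  k2v <- runif(nv, 0.01, 0.06)
  kep <- grid[10]
  conv <- leakage_convolution(dsc_xbar, dsc_time, kep)
  Y <- tcrossprod(k1v, dsc_xbar) - tcrossprod(k2v, conv) +
    matrix(rnorm(nv * length(dsc_time), 0, max(dsc_xbar) / 50), nv)
  fit <- gbmphen:::fit_leakage_matrix(Y, dsc_xbar, dsc_time, grid)
  expect_lt(median(abs(fit$k1 - k1v) / k1v), 0.05)
})
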