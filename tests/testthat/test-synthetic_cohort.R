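test_that("default ground-truth table reproduces the cohort structure", {
  cfg <- cohort_config()
  tb <- generate_cohort_table(cfg)
  expect_equal(nrow(tb), 87)
  expect_equal(sum(tb$phenotype == "high"), 37)
  expect_equal(sum(tb$phenotype == "low"), 50)

  # deterministic covariate allocation: location counts exact per group
  hi <- tb$phenotype == "high"
  expect_equal(sum(tb$location == "frontal" & hi), 7)
  expect_equal(sum(tb$location == "frontal" & !hi), 22)
  expect_equal(sum(tb$location == "temporal" & hi), 13)
  expect_equal(sum(tb$location == "temporal" & !hi), 8)
  expect_equal(sum(tb$sex == "male" & hi), 25)
  expect_equal(sum(tb$sex == "female" & !hi), 22)
  expect_equal(sum(tb$sage_available & hi), 29)
  expect_equal(sum(tb$sage_available & !hi), 39)

  # quantile-matched targets: group medians hit the configured values
  expect_equal(median(tb$target_rcbv[hi]), 1.02, tolerance = 0.02)
  expect_equal(median(tb$target_rcbv[!hi]), 1.28, tolerance = 0.02)
  expect_equal(median(tb$target_mtr[hi]), 2.36, tolerance = 0.02)
  expect_equal(median(tb$target_qt2[!hi]), 100.9, tolerance = 0.02)
  expect_equal(median(tb$volume_cc[hi]), 21.4, tolerance = 0.05)
  expect_equal(median(tb$volume_cc[!hi]), 16.4, tolerance = 0.05)

  # classification margin: every true mu_lo at least 100 from the cutoff
  expect_true(all(abs(tb$mu_lo - 1240) >= 100))
  expect_true(all(tb$mu_hi > tb$mu_lo + 399))

  # different seeds shuffle but preserve structure
  tb2 <- generate_cohort_table(cohort_config(seed = 99))
  expect_equal(sum(tb2$phenotype == "high"), 37)
  expect_false(identical(tb$mu_lo, tb2$mu_lo))

  # degenerate single-group cohort is valid
  tb0 <- generate_cohort_table(cohort_config(n_high = 0, n_low = 5))
  expect_equal(nrow(tb0), 5)
  expect_true(all(tb0$phenotype == "low"))
})

test_that("null preset removes group differences and randomizes sampling", {
  cfg <- cohort_config(null = TRUE)
  expect_equal(cfg$sampling, "random")
  expect_equal(unname(diff(cfg$rcbv$median)), 0)
  expect_equal(unname(diff(cfg$qt2$median)), 0)
  tb <- generate_cohort_table(cfg)
  expect_equal(nrow(tb), 87)
})

test_that("zspectra simulator hits the MTR_asym target analytically", {
  dim3 <- c(4, 4, 1)
  # zero target -> symmetric spectrum -> exactly zero asymmetry
  z0 <- simulate_zspectra(const_vol(0, dim3), const_vol(0, dim3), snr = Inf)
  expect_equal(max(abs(compute_mtr_asym(z0)$data)), 0, tolerance = 1e-12)

  # the printed high-group median, no field, no noise
  z <- simulate_zspectra(const_vol(2.36, dim3), const_vol(0, dim3),
                         snr = Inf)
  expect_equal(as.numeric(compute_mtr_asym(z)$data), rep(2.36, 16),
               tolerance = 0.01 / 2.36)

  # a 0.1 ppm field biases the uncorrected value; correction restores it
  zb <- simulate_zspectra(const_vol(2.36, dim3), const_vol(0.1, dim3),
                          snr = Inf)
  raw <- median(as.numeric(compute_mtr_asym(zb)$data))
  expect_gt(abs(raw - 2.36), 0.1)
  mask <- binary_mask(array(TRUE, dim3))
  cl <- suppressWarnings(cluster_zspectra(zb, mask, n_clusters = 2,
                                          seed = 4))
  corr <- correct_b0(zb, estimate_b0(cl))
  fixed <- median(as.numeric(compute_mtr_asym(corr)$data))
  expect_lt(abs(fixed - 2.36), 0.05)

  expect_error(simulate_zspectra(const_vol(-1, dim3), const_vol(0, dim3)),
               "negative")
})

test_that("DSC simulator round-trips rCBV through the correction", {
  dim3 <- c(60, 1, 1)
  truth <- image_volume(array(c(rep(1, 50), rep(2, 10)), dim3))
  brain <- binary_mask(array(TRUE, dim3), kind = "brain")
  dsc_cfg <- cohort_config()$dsc

  # leak-free, noiseless: normalized map equals the truth (median 1 already)
  s <- simulate_dsc(truth, k2 = 0, kep = 0.01, dsc = dsc_cfg, snr = Inf)
  rcbv <- compute_rcbv(s, brain)
  expect_equal(as.numeric(rcbv$data), as.numeric(truth$data),
               tolerance = 1e-4)

  # leakage in the 'tumor' tail only: corrected recovery within 5%
  k2map <- image_volume(array(c(rep(0, 50), rep(0.05, 10)), dim3))
  s2 <- simulate_dsc(truth, k2 = k2map, kep = 0.02, dsc = dsc_cfg,
                     snr = Inf)
  rcbv2 <- compute_rcbv(s2, brain)
  expect_lt(max(abs(rcbv2$data[51:60] - 2) / 2), 0.05)
  # and the uncorrected integral is visibly biased in those voxels
  d <- signal_to_delta_r2star(s2)
  w <- gbmphen:::trapz_weights(d$time)
  unc <- as.numeric(d$curves %*% w)
  unc <- unc / median(unc)
  expect_gt(max(abs(unc[51:60] - 2) / 2), 0.05)

  # homogeneous truth -> rCBV identically 1
  s3 <- simulate_dsc(const_vol(1, dim3), dsc = dsc_cfg, snr = Inf)
  expect_equal(as.numeric(compute_rcbv(s3, brain)$data), rep(1, 60),
               tolerance = 1e-6)
})

test_that("simulated lesions are internally consistent and RANO-measurable", {
  cfg <- tiny_config()
  tb <- generate_cohort_table(cfg)
  brain <- make_brain_mask(cfg)
  b <- simulate_lesion(cfg, tb[1, ], brain)
  expect_s3_class(b, "lesion_bundle")
  # tumor strictly inside the brain
  expect_false(any(b$tumor$data & !brain$data))
  expect_true(check_rano_measurable(b$tumor))
  # realized volume close to the drawn target (discretization only)
  expect_equal(sum(b$tumor$data) / 1000, tb$volume_cc[1], tolerance = 0.05)
  # regenerating under the same per-lesion seed is bit-identical
  b2 <- simulate_lesion(cfg, tb[1, ], brain)
  expect_identical(b$dwi$s_b0$data, b2$dwi$s_b0$data)
  expect_identical(b$zspectra$signal, b2$zspectra$signal)
})

test_that("on-disk cohorts round-trip through the manifest reader", {
  dir <- withr::local_tempdir()
  cfg <- tiny_config(n_high = 1, n_low = 1)
  cohort <- generate_cohort(cfg, write_dir = dir)
  expect_true(file.exists(file.path(dir, "ground_truth.csv")))
  man <- read.csv(file.path(dir, "manifest.csv"))
  expect_equal(nrow(man), 2)

  b_mem <- cohort$bundle(1)
  b_disk <- read_lesion_bundle(man$path[man$lesion_id ==
                                          cohort$ground_truth$lesion_id[1]],
                               truth = cohort$ground_truth[1, ])
  expect_equal(sum(b_disk$tumor$data), sum(b_mem$tumor$data))
  # float32 storage: signals agree to single precision
  v_mem <- b_mem$dwi$s_b0$data
  v_disk <- b_disk$dwi$s_b0$data
  expect_equal(v_disk[is.finite(v_disk)], v_mem[is.finite(v_mem)],
               tolerance = 1e-6)
  p_mem <- process_lesion(b_mem)
  p_disk <- process_lesion(b_disk)
  expect_equal(p_disk$adc_l, p_mem$adc_l, tolerance = 1e-3)
  expect_equal(p_disk$median_rcbv, p_mem$median_rcbv, tolerance = 1e-3)
})
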