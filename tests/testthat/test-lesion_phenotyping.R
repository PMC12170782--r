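test_that("double-Gaussian fit recovers a well-separated bimodal mixture", {
  set.seed(51)
  x <- c(rnorm(10000, 1000, 150), rnorm(10000, 1800, 250))
  fit <- fit_adc_double_gaussian(x)
  expect_true(fit$converged)
  expect_false(fit$collapsed_to_single)
  expect_equal(fit$mu_lo, 1000, tolerance = 25 / 1000)
  expect_equal(fit$mu_hi, 1800, tolerance = 50 / 1800)
  expect_equal(fit$w_lo + fit$w_hi, 1, tolerance = 1e-6)
  expect_lte(fit$mu_lo, fit$mu_hi)
  expect_lt(fit$adc_l, 1240)
  expect_equal(classify_phenotype(fit$adc_l), "low")
})

test_that("unimodal data collapses to a single Gaussian", {
  set.seed(52)
  x <- rnorm(20000, 1400, 200)
  fit <- fit_adc_double_gaussian(x)
  expect_true(fit$collapsed_to_single)
  expect_equal(fit$adc_l, 1400, tolerance = 25 / 1400)
  expect_error(fit_adc_double_gaussian(rnorm(50, 1000, 100)), "finite ADC")
})

test_that("histogram and EM fits agree on well-separated mixtures", {
  skip_if_not_installed("mclust")
  set.seed(53)
  x <- c(rnorm(8000, 1100, 150), rnorm(12000, 1700, 220))
  f_hist <- fit_adc_double_gaussian(x, method = "histogram")
  f_em <- fit_adc_double_gaussian(x, method = "em")
  expect_lt(abs(f_hist$adc_l - f_em$adc_l), 30)
})

test_that("ADC_L recovery holds across simulated ROIs (property)", {
  set.seed(54)
  n_ok <- 0
  n_rep <- 40
  for (i in seq_len(n_rep)) {
    mu_lo <- runif(1, 800, 1600)
    mu_hi <- mu_lo + runif(1, 400, 800)
    w <- runif(1, 0.2, 0.8)
    n <- 15000
    x <- c(rnorm(round(n * w), mu_lo, runif(1, 120, 200)),
           rnorm(round(n * (1 - w)), mu_hi, runif(1, 200, 300)))
    fit <- fit_adc_double_gaussian(x)
    if (abs(fit$adc_l - mu_lo) < 50) n_ok <- n_ok + 1
  }
  expect_gte(n_ok / n_rep, 0.95)
})

test_that("phenotype classification is boundary-inclusive at 1240", {
  expect_equal(classify_phenotype(1240), "high")
  expect_equal(classify_phenotype(1239.99), "low")
  expect_equal(classify_phenotype(1246), "high")  # the near-cutoff lesion
  expect_equal(classify_phenotype(c(900, 1500)), c("low", "high"))
  expect_error(classify_phenotype(NaN), "non-finite")
})

test_that("RANO measurability uses the 10 mm bounding-box rule", {
  expect_true(check_rano_measurable(ellipsoid_fixture(c(6, 6, 6))))
  expect_false(check_rano_measurable(ellipsoid_fixture(c(6, 6, 4))))
  # thin slab: one dimension under 10 mm fails regardless of the others
  expect_false(check_rano_measurable(ellipsoid_fixture(c(2.5, 15, 15))))
  # anisotropic voxels: 5 voxels at 2.5 mm spacing span >= 10 mm
  arr <- array(FALSE, c(8, 8, 8)); arr[2:6, 2:6, 2:6] <- TRUE
  expect_true(check_rano_measurable(binary_mask(arr,
                                                spacing = c(2.5, 2.5, 2.5))))
  expect_warning(
    flag <- check_rano_measurable(binary_mask(array(FALSE, c(4, 4, 4)))),
    "empty")
  expect_false(flag)
})

test_that("lesion profiles carry ROI medians, volume and covariates", {
  dim3 <- c(30, 30, 30)
  mask <- first_n_mask(21400, dim3)
  set.seed(55)
  adc_arr <- array(NA_real_, dim3)
  adc_arr[seq_len(21400)] <- c(rnorm(11000, 1000, 150),
                               rnorm(10400, 1700, 250))
  maps <- list(adc = image_volume(adc_arr),
               rcbv = const_vol(1.28, dim3),
               mtr_asym = const_vol(2.10, dim3),
               qt2 = const_vol(100.9, dim3))
  prof <- extract_lesion_profile(maps, mask,
                                 clinical = list(lesion_id = "L1",
                                                 location = "frontal"))
  expect_equal(prof$volume_cc, 21.4)
  expect_equal(prof$median_rcbv, 1.28)
  expect_equal(prof$median_mtr_asym, 2.10)
  expect_equal(prof$median_qt2, 100.9)
  expect_true(is.na(prof$median_deltat1))  # missing map -> missing field
  expect_equal(prof$phenotype, "low")
  expect_equal(prof$lesion_id, "L1")

  # NaN voxels excluded from medians
  maps$rcbv$data[1:100] <- NaN
  prof2 <- extract_lesion_profile(maps, mask)
  expect_equal(prof2$median_rcbv, 1.28)

  expect_error(
    extract_lesion_profile(maps, binary_mask(array(FALSE, dim3))), "empty")
})

test_that("frequency maps average masks per group and respect linearity", {
  m1 <- first_n_mask(10, c(6, 6, 6))
  m2 <- first_n_mask(10, c(6, 6, 6))
  fm <- compute_frequency_map(list(m1, m2, m1, m2),
                              rep("high", 4))
  expect_equal(max(fm$high$data), 1)
  expect_equal(sum(fm$high$data), 10)

  arr2 <- array(FALSE, c(6, 6, 6)); arr2[100:109] <- TRUE
  m3 <- binary_mask(arr2)
  fm2 <- compute_frequency_map(list(m1, m3), c("high", "high"))
  expect_equal(sort(unique(as.numeric(fm2$high$data))), c(0, 0.5))

  # group maps weighted by group size recompose the overall frequency map
  masks <- list(m1, m3, m1, m1)
  phen <- c("high", "high", "low", "low")
  fm3 <- compute_frequency_map(masks, phen)
  overall <- Reduce(`+`, lapply(masks, function(m) m$data * 1)) / 4
  recomposed <- (fm3$high$data * 2 + fm3$low$data * 2) / 4
  expect_equal(recomposed, overall, tolerance = 1e-12)
  expect_true(all(fm3$high$data >= 0 & fm3$high$data <= 1))
})
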