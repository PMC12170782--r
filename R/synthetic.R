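#' Default CEST offset sampling scheme
#'
#' Offsets (ppm) sampled densely around the water resonance (0 ppm), the
#' amine resonance (+3 ppm) and the reference frequency (-3 ppm), with a few
#' intermediate points, matching the acquisition style the pipeline expects.
#'
#' @return Sorted numeric vector of 25 offsets in ppm.
#' @export
default_cest_offsets <- function() {
  round(sort(c(seq(-3.4, -2.6, by = 0.2), -2.2, -1.5, -1.2,
               seq(-0.8, 0.8, by = 0.2), 1.2, 1.5, 2.2,
               seq(2.6, 3.4, by = 0.2))), 10)
}

#' Synthetic cohort configuration
#'
#' Defines the statistical structure of the synthetic 87-lesion cohort: group
#' sizes (37 high-ADC_L / 50 low-ADC_L), per-group two-Gaussian ADC mixture
#' parameters, per-group target ROI medians of rCBV (1.02 / 1.28), MTR_asym
#' at 3 ppm (2.36 / 2.10 percent) and qT2 (114.8 / 100.9 ms), lesion volume
#' distributions (medians 21.4 / 16.4 cc), location and clinical covariate
#' counts, forward-model parameters (DSC bolus and leakage, z-spectrum pools,
#' SAGE echo times) and per-modality SNRs. qT2* and deltaT1 carry no group
#' difference and act as negative controls.
#'
#' Per-lesion continuous targets are drawn by quantile-stratified sampling
#' from the group distribution (then shuffled), so sample medians match the
#' configured group medians at any seed; `sampling = "random"` switches to
#' plain random draws. `null = TRUE` removes all group differences and uses
#' random sampling (the preset used for type-I-error calibration).
#'
#' @param n_high,n_low Group sizes.
#' @param cutoff ADC_L classification cutoff in um^2/s.
#' @param seed Base RNG seed; per-lesion seeds are derived from it.
#' @param grid_dim,spacing Common grid (voxels, mm).
#' @param brain_semiaxes Brain ellipsoid semi-axes in mm.
#' @param sampling `"quantile"` (default) or `"random"`.
#' @param null Remove all group differences (type-I calibration preset).
#' @param ... Named overrides of any default component listed below.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_high = 37, n_low = 50, cutoff = 1240, seed = 42,
                          grid_dim = c(96, 96, 96), spacing = c(1, 1, 1),
                          brain_semiaxes = c(40, 44, 36),
                          sampling = c("quantile", "random"),
                          null = FALSE, ...) {
  sampling <- match.arg(sampling)
  cfg <- list(
    n_high = n_high, n_low = n_low, cutoff = cutoff, seed = seed,
    grid_dim = as.integer(grid_dim), spacing = as.numeric(spacing),
    brain_semiaxes = as.numeric(brain_semiaxes), sampling = sampling,
    null = null,
    adc = list(
      mu_lo_mean = c(high = 1450, low = 1020),
      mu_lo_sd = c(high = 110, low = 100),
      mu_lo_range_high = c(1340, 1800), mu_lo_range_low = c(760, 1140),
      sep_range = c(400, 800), w_lo_range = c(0.45, 0.75),
      sigma_lo_range = c(120, 200), sigma_hi_range = c(200, 300),
      brain_mean = 800, brain_sd = 80),
    rcbv = list(median = c(high = 1.02, low = 1.28), sdlog = 0.25,
                voxel_sdlog = 0.15, brain_sdlog = 0.30),
    mtr = list(median = c(high = 2.36, low = 2.10), sd = 0.45,
               voxel_sd = 0.35, brain_mean = 1.2, brain_sd = 0.2,
               min = 0.3),
    qt2 = list(median = c(high = 114.8, low = 100.9), sdlog = 0.12,
               voxel_sdlog = 0.10, brain_median = 85, brain_sdlog = 0.08),
    qt2star = list(median = c(high = 55, low = 55), sdlog = 0.12,
                   voxel_sdlog = 0.10, brain_median = 45,
                   brain_sdlog = 0.08),
    deltat1 = list(enhancement = c(high = 0.5, low = 0.5), sd = 0.12,
                   voxel_sd = 0.10),
    volume = list(median_cc = c(high = 21.4, low = 16.4),
                  sdlog = c(high = 0.706, low = 0.996),
                  cap_cc = c(2, 60), p_range = c(0.05, 0.95)),
    locations = list(
      levels = c("frontal", "temporal", "parietal", "occipital", "other"),
      high = c(7, 13, 12, 3, 2), low = c(22, 8, 12, 5, 3)),
    sex = list(levels = c("male", "female"), high = c(25, 12),
               low = c(28, 22)),
    mgmt = list(levels = c("methylated", "unmethylated", "unknown"),
                high = c(13, 20, 4), low = c(19, 30, 1)),
    egfr = list(levels = c("amplified", "non_amplified", "unknown"),
                high = c(16, 15, 6), low = c(25, 21, 4)),
    age = list(median = c(high = 60, low = 60), iqr = c(high = 12, low = 15)),
    steroid = list(p_zero = 0.6, median_mg = 4, sdlog = 0.5),
    n_sage = c(high = 29, low = 39),
    dsc = list(n_frames = 40L, tr = 1.25, te = 0.035, t0 = 12, alpha = 3,
               tp = 4, peak = 6, s_base = 600, k2_range = c(0.02, 0.06),
               kep_range = c(0.005, 0.05)),
    cest = list(offsets = default_cest_offsets(), water_amp = 0.9,
                water_fwhm = 1.4, amine_fwhm = 1.0, s0_level = 1000,
                b0_amp_range = c(0.03, 0.15)),
    sage = list(te_ms = c(14, 34, 60, 92), te_se_ms = 92),
    dwi = list(b = c(0, 1000), s0_level = 500),
    snr = list(dwi = 40, dsc = 60, cest = 80, sage = 100, t1w = 60),
    n_clusters_b0 = 4)
  dots <- list(...)
  for (nm in names(dots)) {
    if (is.list(cfg[[nm]]) && is.list(dots[[nm]])) {
      cfg[[nm]][names(dots[[nm]])] <- dots[[nm]]
    } else {
      cfg[[nm]] <- dots[[nm]]
    }
  }
  # group-indexed vectors may lose their names through config serialization
  # (e.g. YAML); restore positional high/low naming
  gl <- c("high", "low")
  for (spec in list(c("adc", "mu_lo_mean"), c("adc", "mu_lo_sd"),
                    c("rcbv", "median"), c("mtr", "median"),
                    c("qt2", "median"), c("qt2star", "median"),
                    c("deltat1", "enhancement"), c("volume", "median_cc"),
                    c("volume", "sdlog"), c("age", "median"),
                    c("age", "iqr"))) {
    v <- cfg[[spec[1]]][[spec[2]]]
    if (is.null(names(v))) names(v) <- gl
    cfg[[spec[1]]][[spec[2]]] <- v
  }
  if (is.null(names(cfg$n_sage))) names(cfg$n_sage) <- gl
  if (isTRUE(null)) {
    pool <- function(v) stats::setNames(rep(mean(v), 2), c("high", "low"))
    cfg$rcbv$median <- pool(cfg$rcbv$median)
    cfg$mtr$median <- pool(cfg$mtr$median)
    cfg$qt2$median <- pool(cfg$qt2$median)
    cfg$qt2star$median <- pool(cfg$qt2star$median)
    cfg$deltat1$enhancement <- pool(cfg$deltat1$enhancement)
    cfg$volume$median_cc <- pool(cfg$volume$median_cc)
    cfg$volume$sdlog <- pool(cfg$volume$sdlog)
    cfg$age$median <- pool(cfg$age$median)
    cfg$age$iqr <- pool(cfg$age$iqr)
    cfg$sampling <- "random"
  }
  if (any(c(cfg$n_high, cfg$n_low) < 0) || cfg$n_high + cfg$n_low < 1) {
    stop("cohort_config: invalid group sizes")
  }
  if (cfg$adc$mu_lo_mean["high"] > 4000 || cfg$adc$mu_lo_mean["low"] > 4000) {
    stop("cohort_config: ADC means above the histogram range")
  }
  structure(cfg, class = "cohort_config")
}

# Sampling probabilities: quantile-stratified mid-ranks (shuffled) or plain
# uniform draws. Quantile transform of these gives samples whose median hits
# the distribution median by construction.
sample_probs <- function(n, sampling, p_range = c(0.01, 0.99)) {
  if (n == 0) return(numeric(0))
  if (sampling == "quantile") {
    sample(p_range[1] + diff(p_range) * ((seq_len(n) - 0.5) / n))
  } else {
    stats::runif(n, p_range[1], p_range[2])
  }
}

# Truncated-normal quantile transform.
qnorm_trunc <- function(p, mean, sd, range) {
  plo <- stats::pnorm(range[1], mean, sd)
  phi <- stats::pnorm(range[2], mean, sd)
  stats::qnorm(plo + p * (phi - plo), mean, sd)
}

shuffled_counts <- function(levels, counts) {
  sample(rep(levels, counts))
}

# Rescale configured category counts to a different group size, preserving
# proportions (largest-remainder rounding). Identity when sizes match.
scale_counts <- function(counts, n) {
  if (sum(counts) == n) return(counts)
  raw <- counts / sum(counts) * n
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    add <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[add] <- base[add] + 1
  }
  base
}

# Per-group slice of the ground-truth table. Runs under the caller's RNG.
group_truth <- function(cfg, group, n) {
  if (n == 0) return(NULL)
  s <- cfg$sampling
  adc <- cfg$adc
  rng <- if (group == "high") adc$mu_lo_range_high else adc$mu_lo_range_low
  mu_lo <- qnorm_trunc(sample_probs(n, s), adc$mu_lo_mean[group],
                       adc$mu_lo_sd[group], rng)
  vol_p <- sample_probs(n, s, cfg$volume$p_range)
  vol <- stats::qlnorm(vol_p, log(cfg$volume$median_cc[group]),
                       cfg$volume$sdlog[group])
  vol <- pmin(pmax(vol, cfg$volume$cap_cc[1]), cfg$volume$cap_cc[2])
  age_sd <- cfg$age$iqr[group] / (2 * stats::qnorm(0.75))
  loc <- shuffled_counts(cfg$locations$levels,
                         scale_counts(cfg$locations[[group]], n))
  sex <- shuffled_counts(cfg$sex$levels, scale_counts(cfg$sex[[group]], n))
  mgmt <- shuffled_counts(cfg$mgmt$levels,
                          scale_counts(cfg$mgmt[[group]], n))
  egfr <- shuffled_counts(cfg$egfr$levels,
                          scale_counts(cfg$egfr[[group]], n))
  n_sage <- min(cfg$n_sage[group], n)
  tibble::tibble(
    group = group,
    mu_lo = mu_lo,
    sep = stats::runif(n, adc$sep_range[1], adc$sep_range[2]),
    w_lo = stats::runif(n, adc$w_lo_range[1], adc$w_lo_range[2]),
    sigma_lo = stats::runif(n, adc$sigma_lo_range[1], adc$sigma_lo_range[2]),
    sigma_hi = stats::runif(n, adc$sigma_hi_range[1], adc$sigma_hi_range[2]),
    target_rcbv = stats::qlnorm(sample_probs(n, s),
                                log(cfg$rcbv$median[group]), cfg$rcbv$sdlog),
    target_mtr = pmax(stats::qnorm(sample_probs(n, s), cfg$mtr$median[group],
                                   cfg$mtr$sd), cfg$mtr$min),
    target_qt2 = stats::qlnorm(sample_probs(n, s),
                               log(cfg$qt2$median[group]), cfg$qt2$sdlog),
    target_qt2star = stats::qlnorm(sample_probs(n, s),
                                   log(cfg$qt2star$median[group]),
                                   cfg$qt2star$sdlog),
    target_enh = pmax(stats::qnorm(sample_probs(n, s),
                                   cfg$deltat1$enhancement[group],
                                   cfg$deltat1$sd), 0.05),
    volume_cc = vol,
    age = round(stats::qnorm(sample_probs(n, s), cfg$age$median[group],
                             age_sd)),
    steroid_dose_mg = ifelse(
      stats::runif(n) < cfg$steroid$p_zero, 0,
      round(stats::qlnorm(stats::runif(n), log(cfg$steroid$median_mg),
                          cfg$steroid$sdlog), 1)),
    location = loc,
    sex = sex,
    mgmt = mgmt,
    egfr = egfr,
    # relaxometry subset: systematic over qT2 ranks, so the subset median
    # tracks the group median (same principle as the quantile-matched draws)
    sage_available = {
      n_drop <- n - n_sage
      keep <- rep(TRUE, n)
      if (n_drop > 0) {
        drop_ranks <- pmax(pmin(round((seq_len(n_drop) - 0.5) * n / n_drop),
                                n), 1)
        keep[order(target_qt2)[unique(drop_ranks)]] <- FALSE
        # rounding collisions: drop extras at random ranks
        extra <- n_drop - sum(!keep)
        if (extra > 0) keep[sample(which(keep), extra)] <- FALSE
      }
      keep
    },
    kep = stats::runif(n, cfg$dsc$kep_range[1], cfg$dsc$kep_range[2]),
    k2 = stats::runif(n, cfg$dsc$k2_range[1], cfg$dsc$k2_range[2]),
    b0_amp = stats::runif(n, cfg$cest$b0_amp_range[1],
                          cfg$cest$b0_amp_range[2]))
}

#' Ground-truth table of a synthetic cohort
#'
#' Draws the per-lesion ground truth (ADC mixture parameters, target ROI
#' medians, volume, covariates, forward-model parameters) for the configured
#' cohort, without simulating any image data. Location, sex, MGMT and EGFR
#' counts match the configuration exactly (deterministic allocation shuffled
#' by seed).
#'
#' @param config A [cohort_config()].
#' @return Tibble with one row per lesion, including `mu_hi = mu_lo + sep`,
#'   the true `phenotype`, and a derived per-lesion `sim_seed`.
#' @export
generate_cohort_table <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  tbl <- with_local_seed(config$seed, {
    tb <- dplyr::bind_rows(group_truth(config, "high", config$n_high),
                           group_truth(config, "low", config$n_low))
    tb[sample.int(nrow(tb)), ]
  })
  tbl$lesion_id <- sprintf("L%03d", seq_len(nrow(tbl)))
  tbl$mu_hi <- tbl$mu_lo + tbl$sep
  tbl$phenotype <- classify_phenotype(tbl$mu_lo, config$cutoff)
  tbl$sim_seed <- vapply(seq_len(nrow(tbl)),
                         function(i) derive_seed(config$seed, i), 1L)
  dplyr::relocate(tbl, "lesion_id", "group", "phenotype")
}

#' Analysis-ready view of a ground-truth table
#'
#' Maps generator ground truth onto the column names of a lesion-profile
#' cohort table (`adc_l`, `median_rcbv`, `median_mtr_asym`, `median_qt2`,
#' `median_qt2star`, `median_deltat1`, `volume_cc`, covariates), with qT2 /
#' qT2* missing for lesions lacking SAGE data. Used to exercise the
#' statistical battery directly on ground truth (e.g. null-cohort
#' calibration) without image simulation.
#'
#' @param truth A [generate_cohort_table()] tibble.
#' @return Cohort tibble.
#' @export
ground_truth_profiles <- function(truth) {
  tibble::tibble(
    lesion_id = truth$lesion_id,
    adc_l = truth$mu_lo,
    phenotype = truth$phenotype,
    median_rcbv = truth$target_rcbv,
    median_mtr_asym = truth$target_mtr,
    median_qt2 = ifelse(truth$sage_available, truth$target_qt2, NA_real_),
    median_qt2star = ifelse(truth$sage_available, truth$target_qt2star,
                            NA_real_),
    median_deltat1 = truth$target_enh,
    volume_cc = truth$volume_cc,
    location = truth$location, sex = truth$sex, mgmt = truth$mgmt,
    egfr = truth$egfr, steroid_dose_mg = truth$steroid_dose_mg,
    age = truth$age)
}

# ---- geometry -------------------------------------------------------------

# mm coordinates of every voxel center relative to the grid center.
grid_coords <- function(dim3, spacing) {
  lapply(1:3, function(a) (seq_len(dim3[a]) - (dim3[a] + 1) / 2) * spacing[a])
}

ellipsoid_mask <- function(dim3, spacing, center_mm, semiaxes_mm) {
  co <- grid_coords(dim3, spacing)
  q1 <- ((co[[1]] - center_mm[1]) / semiaxes_mm[1])^2
  q2 <- ((co[[2]] - center_mm[2]) / semiaxes_mm[2])^2
  q3 <- ((co[[3]] - center_mm[3]) / semiaxes_mm[3])^2
  arr <- outer(outer(q1, q2, "+"), q3, "+") <= 1
  arr
}

#' Synthetic brain mask
#'
#' Centered ellipsoid on the common grid.
#'
#' @param config A [cohort_config()].
#' @return A `brain` [binary_mask()].
#' @export
make_brain_mask <- function(config) {
  binary_mask(ellipsoid_mask(config$grid_dim, config$spacing, c(0, 0, 0),
                             config$brain_semiaxes),
              spacing = config$spacing, kind = "brain")
}

# Place a RANO-measurable ellipsoidal tumor of (approximately) the target
# volume fully inside the brain. Runs under the caller's RNG.
make_tumor_mask <- function(config, volume_cc, brain) {
  r <- (3 * volume_cc * 1000 / (4 * pi))^(1 / 3)
  asp <- stats::runif(3, 0.75, 1.3)
  asp <- asp / prod(asp)^(1 / 3)
  semi <- pmax(r * asp, 5.2)
  B <- config$brain_semiaxes
  for (attempt in 1:25) {
    shrink <- 0.97^(attempt - 1)
    lim <- pmax((B - semi - 1) * shrink, 0)
    ctr <- stats::runif(3, -lim, lim)
    arr <- ellipsoid_mask(config$grid_dim, config$spacing, ctr, semi)
    if (!any(arr & !brain$data)) {
      return(binary_mask(arr, config$spacing, kind = "tumor_ce"))
    }
  }
  arr <- ellipsoid_mask(config$grid_dim, config$spacing, c(0, 0, 0), semi)
  binary_mask(arr & brain$data, config$spacing, kind = "tumor_ce")
}

# ---- forward simulators ---------------------------------------------------

# Lorentzian lineshape on unit amplitude.
lorentz <- function(delta_ppm, fwhm) {
  (fwhm / 2)^2 / ((fwhm / 2)^2 + delta_ppm^2)
}

#' Forward-simulate a two-b-value DWI pair
#'
#' `S_b1000 = s0_level * exp(-b * ADC * 1e-6)` plus additive Gaussian noise
#' of standard deviation `s0_level / snr` on both signals (a magnitude-noise
#' approximation valid at the SNRs used here).
#'
#' @param adc_truth ADC ground truth in um^2/s, an [image_volume()].
#' @param s0_level Baseline signal level (a.u.).
#' @param snr Signal-to-noise ratio; `Inf` for noiseless.
#' @param b The two b-values in s/mm^2.
#' @return A [dwi_pair()].
#' @export
simulate_dwi <- function(adc_truth, s0_level = 500, snr = 40,
                         b = c(0, 1000)) {
  if (!is.numeric(snr) || snr <= 0) stop("simulate_dwi: snr must be positive")
  sig <- sim_dwi_core(as.numeric(adc_truth$data), s0_level, snr, b)
  mk <- function(v) image_volume(array(v, dim(adc_truth$data)),
                                 adc_truth$spacing, adc_truth$frame_id)
  dwi_pair(mk(sig$s_b0), mk(sig$s_b1000), b_low = b[1], b_high = b[2])
}

sim_dwi_core <- function(adc, s0_level, snr, b = c(0, 1000)) {
  n <- length(adc)
  noise_sd <- if (is.finite(snr)) s0_level / snr else 0
  s0 <- s0_level * exp(-b[1] * adc * 1e-6) + stats::rnorm(n, 0, noise_sd)
  s1 <- s0_level * exp(-b[2] * adc * 1e-6) + stats::rnorm(n, 0, noise_sd)
  list(s_b0 = s0, s_b1000 = s1)
}

# Band-mean asymmetry of a unit-amplitude amine Lorentzian at +3 ppm,
# evaluated on the sampled offsets: the linear factor relating the amine
# amplitude to the band-integrated MTR_asym.
amine_band_factor <- function(offsets, amine_fwhm, band_center = 3,
                              band_halfwidth = 0.2) {
  band <- offsets[offsets >= band_center - band_halfwidth - 1e-9 &
                    offsets <= band_center + band_halfwidth + 1e-9]
  mean(lorentz(band - band_center, amine_fwhm) -
         lorentz(-band - band_center, amine_fwhm))
}

sim_zspectra_core <- function(mtr_pct, b0_ppm, offsets, snr, water_amp,
                              water_fwhm, amine_fwhm, s0_level) {
  if (any(mtr_pct < 0, na.rm = TRUE)) {
    stop("simulate_zspectra: negative MTR_asym target")
  }
  cfac <- amine_band_factor(offsets, amine_fwhm)
  a <- (mtr_pct / 100) / cfac
  n <- length(mtr_pct)
  Z <- matrix(0, n, length(offsets))
  for (k in seq_along(offsets)) {
    Z[, k] <- 1 - water_amp * lorentz(offsets[k] - b0_ppm, water_fwhm) -
      a * lorentz(offsets[k] - 3 - b0_ppm, amine_fwhm)
  }
  noise_sd <- if (is.finite(snr)) s0_level / snr else 0
  sig <- s0_level * Z
  if (noise_sd > 0) {
    sig <- sig + matrix(stats::rnorm(length(sig), 0, noise_sd), n)
  }
  s0 <- s0_level + stats::rnorm(n, 0, noise_sd)
  list(signal = sig, s0 = s0)
}

#' Forward-simulate a CEST z-spectrum series
#'
#' Two-pool phenomenological model: a water direct-saturation Lorentzian
#' centered at the local DeltaB0 and an amine Lorentzian at DeltaB0 + 3 ppm
#' whose amplitude is solved analytically (the band-integrated asymmetry is
#' linear in it) so that the B0-corrected MTR_asym at 3 ppm equals the target.
#' Saturation physics is not simulated.
#'
#' @param mtr_target Target MTR_asym map in percent, an [image_volume()].
#' @param b0_field DeltaB0 field in ppm, an [image_volume()].
#' @param offsets Offset scheme in ppm.
#' @param snr Signal-to-noise ratio; `Inf` for noiseless.
#' @param water_amp,water_fwhm,amine_fwhm Pool parameters (fraction, ppm).
#' @param s0_level Unsaturated signal level (a.u.).
#' @return A [zspectrum_series()].
#' @export
simulate_zspectra <- function(mtr_target, b0_field,
                              offsets = default_cest_offsets(), snr = 80,
                              water_amp = 0.9, water_fwhm = 1.4,
                              amine_fwhm = 1.0, s0_level = 1000) {
  assert_same_grid(mtr_target, b0_field, "MTR target and B0 field")
  sim <- sim_zspectra_core(as.numeric(mtr_target$data),
                           as.numeric(b0_field$data), offsets, snr,
                           water_amp, water_fwhm, amine_fwhm, s0_level)
  dim4 <- c(dim(mtr_target$data), length(offsets))
  zspectrum_series(array(sim$signal, dim4), offsets,
                   image_volume(array(sim$s0, dim(mtr_target$data)),
                                mtr_target$spacing, mtr_target$frame_id),
                   spacing = mtr_target$spacing,
                   frame_id = mtr_target$frame_id)
}

sim_sage_core <- function(qt2_ms, qt2star_ms, te_ms, te_se_ms, snr,
                          s0_level = 1000) {
  r2 <- 1000 / qt2_ms
  r2star <- 1000 / qt2star_ms
  S <- sage_forward(s0_level, s0_level, r2, r2star, te_ms, te_se_ms)
  noise_sd <- if (is.finite(snr)) s0_level / snr else 0
  if (noise_sd > 0) {
    S <- S + matrix(stats::rnorm(length(S), 0, noise_sd), nrow(S))
  }
  S
}

#' Forward-simulate a SAGE echo set
#'
#' Evaluates the piecewise gradient/spin-echo signal equations at the
#' configured echo times. Voxels with `qT2* > qT2` are physically implausible
#' but generated as-is (a warning is emitted), exercising the solver's
#' flag-only policy.
#'
#' @param qt2_truth,qt2star_truth Ground-truth maps in ms ([image_volume()]).
#' @param te_ms Echo times in ms; `te_se_ms` spin-echo time.
#' @param te_se_ms Spin-echo time in ms.
#' @param snr Signal-to-noise ratio; `Inf` for noiseless.
#' @param s0_level Signal level (a.u.).
#' @return A [sage_echo_set()].
#' @export
simulate_sage <- function(qt2_truth, qt2star_truth,
                          te_ms = c(14, 34, 60, 92), te_se_ms = 92,
                          snr = 100, s0_level = 1000) {
  assert_same_grid(qt2_truth, qt2star_truth, "qT2 and qT2* truths")
  q2 <- as.numeric(qt2_truth$data)
  q2s <- as.numeric(qt2star_truth$data)
  if (any(q2s > q2, na.rm = TRUE)) {
    warning("simulate_sage: ", sum(q2s > q2, na.rm = TRUE),
            " voxel(s) with qT2* > qT2 (generated as-is)")
  }
  S <- sim_sage_core(q2, q2s, te_ms, te_se_ms, snr, s0_level)
  vols <- lapply(1:4, function(j) {
    image_volume(array(S[, j], dim(qt2_truth$data)), qt2_truth$spacing,
                 qt2_truth$frame_id)
  })
  sage_echo_set(vols, te_ms, te_se_ms)
}

# Gamma-variate bolus curve (peak Delta-R2* in 1/s at the configured peak).
gamma_variate <- function(t, t0, alpha, tp, peak) {
  tt <- pmax(t - t0, 0) / tp
  peak * tt^alpha * exp(alpha * (1 - tt))
}

sim_dsc_core <- function(rcbv, k2_voxel, kep, dsc_cfg, snr) {
  t <- (seq_len(dsc_cfg$n_frames) - 1) * dsc_cfg$tr
  xbar <- gamma_variate(t, dsc_cfg$t0, dsc_cfg$alpha, dsc_cfg$tp,
                        dsc_cfg$peak)
  conv <- leakage_convolution(xbar, t, kep)
  meas <- tcrossprod(rcbv, xbar) - tcrossprod(k2_voxel, conv)
  sig <- dsc_cfg$s_base * exp(-dsc_cfg$te * meas)
  noise_sd <- if (is.finite(snr)) dsc_cfg$s_base / snr else 0
  if (noise_sd > 0) {
    sig <- sig + matrix(stats::rnorm(length(sig), 0, noise_sd), nrow(sig))
  }
  list(signal = sig, time = t, xbar = xbar,
       baseline_idx = which(t < dsc_cfg$t0))
}

#' Forward-simulate a DSC signal series
#'
#' The reference bolus `xbar(t)` is a gamma-variate; each voxel's Delta-R2*
#' curve is `rcbv_truth * xbar(t) - k2 * conv(xbar, kep)(t)` (so the
#' leak-free time integral is proportional to the rCBV truth), converted to
#' signal by `S = s_base * exp(-TE * DeltaR2*)` with additive Gaussian noise.
#'
#' @param rcbv_truth Ground-truth relative blood volume ([image_volume()]).
#' @param k2 Leakage amplitude map (1/s): [image_volume()] or scalar.
#' @param kep Efflux rate (1/s), shared across voxels.
#' @param dsc Named list of bolus/readout parameters (see [cohort_config()]
#'   `$dsc` for the fields and defaults).
#' @param snr Signal-to-noise ratio; `Inf` for noiseless.
#' @return A [dsc_series()] with `baseline_idx` set to the pre-bolus frames.
#' @export
simulate_dsc <- function(rcbv_truth, k2 = 0, kep = 0.01,
                         dsc = cohort_config()$dsc, snr = 60) {
  rv <- as.numeric(rcbv_truth$data)
  k2v <- if (inherits(k2, "image_volume")) as.numeric(k2$data) else
    rep(k2, length(rv))
  sim <- sim_dsc_core(rv, k2v, kep, dsc, snr)
  dim4 <- c(dim(rcbv_truth$data), dsc$n_frames)
  dsc_series(array(sim$signal, dim4), tr = dsc$tr, te = dsc$te,
             baseline_idx = sim$baseline_idx, spacing = rcbv_truth$spacing,
             frame_id = rcbv_truth$frame_id)
}

# ---- per-lesion bundle ----------------------------------------------------

# Smooth low-order polynomial field over the brain, scaled to max |amp| ppm.
smooth_b0_field <- function(brain_idx, dim3, spacing, semiaxes, amp) {
  co <- grid_coords(dim3, spacing)
  ijk <- arrayInd(brain_idx, dim3)
  x <- co[[1]][ijk[, 1]] / semiaxes[1]
  y <- co[[2]][ijk[, 2]] / semiaxes[2]
  z <- co[[3]][ijk[, 3]] / semiaxes[3]
  cf <- stats::rnorm(7)
  f <- cf[1] * x + cf[2] * y + cf[3] * z + cf[4] * x * y + cf[5] * x * z +
    cf[6] * y * z + cf[7] * (x^2 - y^2)
  m <- max(abs(f))
  if (m < 1e-9) rep(0, length(f)) else f / m * amp
}

# Multiplicative voxel spread with sample median exactly 1.
median_one_spread <- function(n, sdlog) {
  e <- exp(stats::rnorm(n, 0, sdlog))
  e / stats::median(e)
}

#' Simulate one lesion's raw data bundle
#'
#' Builds the lesion's tumor mask and per-voxel ground-truth fields on the
#' shared brain, then forward-simulates every modality: DWI pair, DSC series,
#' CEST z-spectra (with a smooth DeltaB0 field), SAGE echoes (when the lesion
#' has relaxometry), and pre/post-contrast T1-weighted images. All 4D series
#' use the masked voxel-by-frame representation restricted to the brain.
#' Reproducible via the per-lesion `sim_seed` in the ground-truth row.
#'
#' @param config A [cohort_config()].
#' @param truth_row One row of [generate_cohort_table()].
#' @param brain Shared brain [binary_mask()] from [make_brain_mask()].
#' @return List of class `lesion_bundle`: `tumor`, `brain`, `dwi`, `dsc`,
#'   `zspectra`, `sage` (or `NULL`), `t1w_pre`, `t1w_post`, `truth`.
#' @export
simulate_lesion <- function(config, truth_row, brain = make_brain_mask(config)) {
  stopifnot(inherits(config, "cohort_config"), nrow(truth_row) == 1)
  with_local_seed(truth_row$sim_seed, {
    dim3 <- config$grid_dim
    sp <- config$spacing
    bidx <- which(brain$data)
    nb <- length(bidx)
    tumor <- make_tumor_mask(config, truth_row$volume_cc, brain)
    tpos <- match(which(tumor$data), bidx)
    nt <- length(tpos)

    # ground-truth voxel fields over brain voxels
    adc <- stats::rnorm(nb, config$adc$brain_mean, config$adc$brain_sd)
    comp_lo <- stats::runif(nt) < truth_row$w_lo
    adc[tpos] <- ifelse(comp_lo,
                        stats::rnorm(nt, truth_row$mu_lo, truth_row$sigma_lo),
                        stats::rnorm(nt, truth_row$mu_hi, truth_row$sigma_hi))
    adc <- pmin(pmax(adc, 60), 3900)

    # rCBV truth calibrated so the tumor median equals its target AFTER
    # whole-brain-median normalization (the tumor is part of the brain, so
    # the naive construction would bias the normalized ROI median)
    rcbv <- exp(stats::rnorm(nb, 0, config$rcbv$brain_sdlog))
    rcbv <- rcbv / stats::median(rcbv)
    tum_vals <- truth_row$target_rcbv *
      median_one_spread(nt, config$rcbv$voxel_sdlog)
    cal <- stats::uniroot(function(cc) {
      stats::median(c(rcbv[-tpos] * cc, tum_vals)) - 1
    }, c(0.5, 2), tol = 1e-6)$root
    rcbv[-tpos] <- rcbv[-tpos] * cal
    rcbv[tpos] <- tum_vals

    mtr <- stats::rnorm(nb, config$mtr$brain_mean, config$mtr$brain_sd)
    e <- stats::rnorm(nt, 0, config$mtr$voxel_sd)
    mtr[tpos] <- truth_row$target_mtr + (e - stats::median(e))
    mtr <- pmax(mtr, 0.05)

    qt2 <- config$qt2$brain_median *
      exp(stats::rnorm(nb, 0, config$qt2$brain_sdlog))
    qt2[tpos] <- truth_row$target_qt2 *
      median_one_spread(nt, config$qt2$voxel_sdlog)
    qt2star <- config$qt2star$brain_median *
      exp(stats::rnorm(nb, 0, config$qt2star$brain_sdlog))
    qt2star[tpos] <- truth_row$target_qt2star *
      median_one_spread(nt, config$qt2star$voxel_sdlog)

    k2v <- rep(0, nb)
    k2v[tpos] <- truth_row$k2 * stats::runif(nt, 0.5, 1.5)

    b0 <- smooth_b0_field(bidx, dim3, sp, config$brain_semiaxes,
                          truth_row$b0_amp)

    # modalities
    dwi_sig <- sim_dwi_core(adc, config$dwi$s0_level, config$snr$dwi,
                            config$dwi$b)
    full <- function(v) {
      arr <- array(NA_real_, dim3)
      arr[bidx] <- v
      image_volume(arr, sp)
    }
    dwi <- dwi_pair(full(dwi_sig$s_b0), full(dwi_sig$s_b1000),
                    b_low = config$dwi$b[1], b_high = config$dwi$b[2])

    dsc_sim <- sim_dsc_core(rcbv, k2v, truth_row$kep, config$dsc,
                            config$snr$dsc)
    dsc <- dsc_series(dsc_sim$signal, tr = config$dsc$tr, te = config$dsc$te,
                      baseline_idx = dsc_sim$baseline_idx, spacing = sp,
                      voxels = bidx, dim3 = dim3)

    z_sim <- sim_zspectra_core(mtr, b0, config$cest$offsets,
                               config$snr$cest, config$cest$water_amp,
                               config$cest$water_fwhm,
                               config$cest$amine_fwhm, config$cest$s0_level)
    zspectra <- zspectrum_series(z_sim$signal, config$cest$offsets,
                                 z_sim$s0, spacing = sp, voxels = bidx,
                                 dim3 = dim3)

    sage <- NULL
    if (isTRUE(truth_row$sage_available)) {
      S <- sim_sage_core(qt2, qt2star, config$sage$te_ms,
                         config$sage$te_se_ms, config$snr$sage)
      sage <- sage_echo_set(S, config$sage$te_ms, config$sage$te_se_ms,
                            voxels = bidx, dim3 = dim3, spacing = sp)
    }

    base <- 1000 * (1 + stats::rnorm(nb, 0, 0.03))
    enh <- rep(0, nb)
    enh[tpos] <- pmax(truth_row$target_enh +
                        stats::rnorm(nt, 0, config$deltat1$voxel_sd), 0)
    noise_sd <- 1000 / config$snr$t1w
    t1w_pre <- full(base + stats::rnorm(nb, 0, noise_sd))
    t1w_post <- full(base * (1 + enh) + stats::rnorm(nb, 0, noise_sd))

    structure(list(tumor = tumor, brain = brain, dwi = dwi, dsc = dsc,
                   zspectra = zspectra, sage = sage, t1w_pre = t1w_pre,
                   t1w_post = t1w_post, truth = truth_row,
                   b0_truth = b0),
              class = "lesion_bundle")
  })
}

#' Generate a synthetic cohort
#'
#' Draws the ground-truth table and returns a lazy cohort object whose
#' `bundle(i)` method simulates lesion `i`'s raw data on demand (bundles are
#' large, so they are not all held in memory). With `write_dir`, every
#' bundle is written to disk as NIfTI volumes plus JSON sidecars, with
#' `manifest.csv` and `ground_truth.csv` alongside.
#'
#' @param config A [cohort_config()].
#' @param write_dir Optional output directory.
#' @return Object of class `synthetic_cohort`: `ground_truth`, `config`,
#'   `brain`, and the `bundle(i)` accessor.
#' @export
generate_cohort <- function(config, write_dir = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  truth <- generate_cohort_table(config)
  brain <- make_brain_mask(config)
  bundle <- function(i) simulate_lesion(config, truth[i, ], brain)
  obj <- structure(list(ground_truth = truth, config = config, brain = brain,
                        bundle = bundle),
                   class = "synthetic_cohort")
  if (!is.null(write_dir)) write_cohort(obj, write_dir)
  obj
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort> ", nrow(x$ground_truth), " lesions (",
      sum(x$ground_truth$phenotype == "high"), " high / ",
      sum(x$ground_truth$phenotype == "low"), " low ADC_L), grid ",
      paste(x$config$grid_dim, collapse = "x"), "\n", sep = "")
  invisible(x)
}

# Expand a masked series to a dense 4D array (for on-disk bundles).
dense_series <- function(mat, voxels, dim3) {
  arr <- array(NA_real_, c(dim3, ncol(mat)))
  n3 <- prod(dim3)
  for (j in seq_len(ncol(mat))) arr[voxels + (j - 1) * n3] <- mat[, j]
  arr
}

write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  truth <- cohort$ground_truth
  utils::write.csv(truth, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE)
  rows <- vector("list", nrow(truth))
  for (i in seq_len(nrow(truth))) {
    b <- cohort$bundle(i)
    ldir <- file.path(dir, truth$lesion_id[i])
    dir.create(ldir, showWarnings = FALSE)
    sp <- cohort$config$spacing
    d3 <- cohort$config$grid_dim
    wr4 <- function(mat, voxels, name) {
      arr <- dense_series(mat, voxels, d3)
      img <- RNifti::asNifti(arr)
      RNifti::pixdim(img) <- sp
      RNifti::writeNifti(img, file.path(ldir, name), datatype = "float")
    }
    write_volume(b$tumor, file.path(ldir, "tumor.nii.gz"))
    write_volume(b$brain, file.path(ldir, "brain.nii.gz"))
    write_volume(b$dwi$s_b0, file.path(ldir, "dwi_b0.nii.gz"))
    write_volume(b$dwi$s_b1000, file.path(ldir, "dwi_b1000.nii.gz"))
    write_volume(b$t1w_pre, file.path(ldir, "t1w_pre.nii.gz"))
    write_volume(b$t1w_post, file.path(ldir, "t1w_post.nii.gz"))
    wr4(b$dsc$signal, b$dsc$voxels, "dsc.nii.gz")
    jsonlite::write_json(list(tr = b$dsc$tr, te = b$dsc$te,
                              baseline_idx = b$dsc$baseline_idx),
                         file.path(ldir, "dsc.json"), auto_unbox = TRUE)
    wr4(b$zspectra$signal, b$zspectra$voxels, "cest.nii.gz")
    s0arr <- array(NA_real_, d3)
    s0arr[b$zspectra$voxels] <- b$zspectra$s0
    write_volume(image_volume(s0arr, sp), file.path(ldir, "cest_s0.nii.gz"))
    jsonlite::write_json(list(offsets_ppm = b$zspectra$offsets_ppm),
                         file.path(ldir, "cest.json"), auto_unbox = TRUE)
    if (!is.null(b$sage)) {
      wr4(b$sage$signal, b$sage$voxels, "sage.nii.gz")
      jsonlite::write_json(list(te_ms = b$sage$te_ms,
                                te_se_ms = b$sage$te_se_ms),
                           file.path(ldir, "sage.json"), auto_unbox = TRUE)
    }
    rows[[i]] <- data.frame(lesion_id = truth$lesion_id[i], path = ldir,
                            sage_available = !is.null(b$sage))
  }
  utils::write.csv(do.call(rbind, rows), file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(dir)
}
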