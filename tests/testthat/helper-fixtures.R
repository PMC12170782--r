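# Shared fixture builders; everything is generated in code at test time.

const_vol <- function(value, dim3 = c(4, 4, 4), spacing = c(1, 1, 1)) {
  image_volume(array(value, dim3), spacing = spacing)
}

# Cuboid mask of `n` voxels filled in array order.
first_n_mask <- function(n, dim3 = c(10, 10, 10), spacing = c(1, 1, 1),
                         kind = "tumor_ce") {
  arr <- array(FALSE, dim3)
  arr[seq_len(n)] <- TRUE
  binary_mask(arr, spacing = spacing, kind = kind)
}

# Centered ellipsoid mask with semi-axes in mm.
ellipsoid_fixture <- function(semi_mm, dim3 = c(32, 32, 32),
                              spacing = c(1, 1, 1), kind = "tumor_ce") {
  co <- lapply(1:3, function(a) {
    (seq_len(dim3[a]) - (dim3[a] + 1) / 2) * spacing[a]
  })
  arr <- outer(outer((co[[1]] / semi_mm[1])^2, (co[[2]] / semi_mm[2])^2,
                     "+"), (co[[3]] / semi_mm[3])^2, "+") <= 1
  binary_mask(arr, spacing = spacing, kind = kind)
}

# Small-but-complete cohort configuration for pipeline-level tests: coarse
# grid, small brain, few lesions; group structure preserved.
tiny_config <- function(n_high = 3, n_low = 3, seed = 7, ...) {
  cohort_config(
    n_high = n_high, n_low = n_low, seed = seed,
    grid_dim = c(40, 40, 40), brain_semiaxes = c(16, 17, 15),
    volume = list(median_cc = c(high = 4, low = 3.5),
                  sdlog = c(high = 0.25, low = 0.25),
                  cap_cc = c(2, 7), p_range = c(0.05, 0.95)),
    n_sage = c(high = n_high, low = n_low), ...)
}

# Analytic two-pool z-spectrum used as a CEST oracle: water Lorentzian at
# `b0` plus an amine Lorentzian at b0 + 3 ppm.
two_pool_spectrum <- function(offsets, amine_amp, b0 = 0, water_amp = 0.9,
                              water_fwhm = 1.4, amine_fwhm = 1.0) {
  lor <- function(d, g) (g / 2)^2 / ((g / 2)^2 + d^2)
  1 - water_amp * lor(offsets - b0, water_fwhm) -
    amine_amp * lor(offsets - 3 - b0, amine_fwhm)
}

# Build a zspectrum_series from a voxel-by-offset matrix on a flat grid.
spectra_series <- function(Z, offsets, s0_level = 1) {
  nv <- nrow(Z)
  dim3 <- c(nv, 1, 1)
  zspectrum_series(array(Z * s0_level, c(dim3, length(offsets))), offsets,
                   image_volume(array(s0_level, dim3)))
}
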