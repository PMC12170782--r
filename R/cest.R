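#' CEST z-spectrum series
#'
#' Per-voxel saturation spectra over a set of frequency offsets, plus the
#' unsaturated reference image `s0`. The offset scheme must sample densely
#' around the amine resonance (+3 ppm), the reference frequency (-3 ppm) and
#' the water resonance (0 ppm): at least three offsets in each of
#' `[-3.2, -2.8]`, `[2.8, 3.2]` and `[-0.75, 0.75]`.
#'
#' @param signal 4D array `(x, y, z, offset)` or a voxel-by-offset matrix
#'   (masked representation; then give `voxels` and `dim3`).
#' @param offsets_ppm Strictly increasing offsets in ppm.
#' @param s0 Unsaturated reference: an [image_volume()] or, for a masked
#'   series, a numeric vector aligned with the matrix rows.
#' @param spacing Voxel spacing in mm.
#' @param voxels,dim3 Masked-representation metadata.
#' @param frame_id Common-grid identifier.
#' @return An object of class `zspectrum_series`.
#' @export
zspectrum_series <- function(signal, offsets_ppm, s0, spacing = c(1, 1, 1),
                             voxels = NULL, dim3 = NULL,
                             frame_id = "common") {
  sm <- series_matrix(signal, voxels, dim3)
  offsets_ppm <- as.numeric(offsets_ppm)
  if (length(offsets_ppm) != ncol(sm$mat)) {
    stop("zspectrum_series: one offset per frame required")
  }
  if (any(diff(offsets_ppm) <= 0)) {
    stop("zspectrum_series: offsets must be strictly increasing")
  }
  for (band in list(c(-3.2, -2.8), c(2.8, 3.2), c(-0.75, 0.75))) {
    if (sum(offsets_ppm >= band[1] & offsets_ppm <= band[2]) < 3) {
      stop("zspectrum_series: need >= 3 offsets in [",
           band[1], ", ", band[2], "] ppm")
    }
  }
  s0v <- if (inherits(s0, "image_volume")) {
    if (is.null(sm$voxels)) as.numeric(s0$data) else s0$data[sm$voxels]
  } else as.numeric(s0)
  if (length(s0v) != nrow(sm$mat)) {
    stop("zspectrum_series: s0 does not match the series voxels")
  }
  structure(list(signal = sm$mat, offsets_ppm = offsets_ppm, s0 = s0v,
                 voxels = sm$voxels, dim3 = sm$dim3,
                 spacing = as.numeric(spacing), frame_id = frame_id),
            class = "zspectrum_series")
}

#' k-means clustering of z-spectra
#'
#' Normalizes each voxel's spectrum by its unsaturated reference and groups
#' the spectrum vectors by k-means. Clustering is the first half of the
#' B0-correction scheme: voxels sharing a field offset have congruent spectra
#' and land in the same cluster, whose centroid is then fit with a Lorentzian
#' (see [estimate_b0()]). For large masks the centroids are estimated on a
#' random subsample and every voxel is then assigned to its nearest centroid;
#' results are deterministic under a fixed `seed`.
#'
#' @param series A [zspectrum_series()].
#' @param mask [binary_mask()] of voxels to cluster (typically brain).
#' @param n_clusters Number of clusters (default 4).
#' @param seed RNG seed for centroid initialization and subsampling.
#' @param max_fit_voxels Subsample size for centroid estimation.
#' @return An object of class `zspec_clusters`: `labels` (per masked voxel),
#'   `voxels`, `centroids` (cluster-by-offset matrix of normalized spectra),
#'   `offsets_ppm`, `n_clusters`.
#' @export
cluster_zspectra <- function(series, mask, n_clusters = 4, seed = 1,
                             max_fit_voxels = 20000L) {
  stopifnot(inherits(series, "zspectrum_series"),
            inherits(mask, "binary_mask"))
  sel <- mask_rows(list(mat = series$signal, voxels = series$voxels,
                        dim3 = series$dim3), mask)
  s0 <- series$s0[sel$rows]
  ok <- is.finite(s0) & s0 > 0
  Z <- series$signal[sel$rows[ok], , drop = FALSE] / s0[ok]
  if (nrow(Z) < n_clusters) {
    stop("cluster_zspectra: fewer usable voxels (", nrow(Z),
         ") than clusters (", n_clusters, ")")
  }
  km <- with_local_seed(seed, {
    fit_rows <- if (nrow(Z) > max_fit_voxels) {
      sample.int(nrow(Z), max_fit_voxels)
    } else seq_len(nrow(Z))
    Zs <- Z[fit_rows, , drop = FALSE]
    res <- NULL
    k_try <- n_clusters
    while (is.null(res) && k_try > 1L) {
      res <- tryCatch(
        suppressWarnings(stats::kmeans(Zs, centers = k_try, nstart = 5,
                                       iter.max = 50,
                                       algorithm = "Lloyd")),
        error = function(e) NULL)  # fewer distinct spectra than centers
      if (is.null(res)) k_try <- k_try - 1L
    }
    if (is.null(res)) res <- list(centers = matrix(colMeans(Zs), 1))
    res
  })
  centroids <- km$centers
  k_eff <- nrow(centroids)
  if (k_eff < n_clusters) {
    warning("cluster_zspectra: spectra support only ", k_eff, " cluster(s)")
  }
  # assign every voxel (not just the subsample) to the nearest centroid
  d2 <- outer(rowSums(Z^2), rowSums(centroids^2), "+") -
    2 * Z %*% t(centroids)
  lab_ok <- max.col(-d2, ties.method = "first")
  labels <- rep(NA_integer_, length(sel$rows))
  labels[ok] <- lab_ok
  structure(list(labels = labels, voxels = sel$voxels, centroids = centroids,
                 offsets_ppm = series$offsets_ppm, n_clusters = k_eff,
                 dim3 = series$dim3 %||% dim(mask$data),
                 spacing = series$spacing, frame_id = series$frame_id),
            class = "zspec_clusters")
}

#' Single-pool Lorentzian fit of a z-spectrum
#'
#' Fits `L(w) = 1 - A * (G/2)^2 / ((G/2)^2 + (w - c)^2)` to the normalized
#' spectrum over `|w| <= window` ppm by bounded nonlinear least squares. The
#' fitted center `c` is the local static-field offset DeltaB0.
#'
#' @param offsets_ppm Offsets in ppm.
#' @param z Normalized spectrum values (fractions of s0).
#' @param window Half-width of the fit window around 0 ppm (default 1.5).
#' @param center_bound Bound on `|c|` in ppm (default 1).
#' @return An object of class `lorentzian_fit` with `amplitude`, `fwhm`,
#'   `center`, `rss`, `converged`.
#' @export
fit_lorentzian <- function(offsets_ppm, z, window = 1.5, center_bound = 1) {
  inw <- abs(offsets_ppm) <= window
  if (sum(inw) < 4) stop("fit_lorentzian: fewer than 4 offsets in window")
  w <- offsets_ppm[inw]
  y <- z[inw]
  c0 <- w[which.min(y)]
  c0 <- min(max(c0, -center_bound + 1e-3), center_bound - 1e-3)
  start <- list(A = max(1 - min(y), 0.1), G = 1, cc = c0)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ 1 - A * (G / 2)^2 / ((G / 2)^2 + (w - cc)^2),
      start = start,
      lower = c(A = 0.02, G = 0.1, cc = -center_bound),
      upper = c(A = 1.5, G = 6, cc = center_bound),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(amplitude = NA_real_, fwhm = NA_real_,
                          center = NA_real_, rss = NA_real_,
                          converged = FALSE),
                     class = "lorentzian_fit"))
  }
  cf <- stats::coef(fit)
  structure(list(amplitude = unname(cf["A"]), fwhm = unname(cf["G"]),
                 center = unname(cf["cc"]),
                 rss = sum(stats::resid(fit)^2), converged = TRUE),
            class = "lorentzian_fit")
}

#' Static-field offset (DeltaB0) map from clustered z-spectra
#'
#' Fits a single-pool Lorentzian to each cluster centroid over the water
#' window; the fitted center is the cluster's DeltaB0 and every voxel
#' inherits its cluster's value. Voxels whose `|DeltaB0|` exceeds the
#' exclusion threshold (default 0.3 ppm), or whose centroid fit failed, are
#' flagged.
#'
#' @param clusters A [cluster_zspectra()] result.
#' @param threshold Flagging threshold in ppm (default 0.3).
#' @param window,center_bound Passed to [fit_lorentzian()].
#' @return An object of class `b0_map`: `delta_b0` (per-voxel ppm), `flagged`
#'   (logical), `voxels`, `cluster_fits` (tibble), plus grid metadata.
#' @export
estimate_b0 <- function(clusters, threshold = 0.3, window = 1.5,
                        center_bound = 1) {
  stopifnot(inherits(clusters, "zspec_clusters"))
  k <- nrow(clusters$centroids)
  fits <- vector("list", k)
  centers <- rep(NA_real_, k)
  for (j in seq_len(k)) {
    fits[[j]] <- fit_lorentzian(clusters$offsets_ppm, clusters$centroids[j, ],
                                window = window, center_bound = center_bound)
    if (fits[[j]]$converged) centers[j] <- fits[[j]]$center
  }
  if (anyNA(centers)) {
    vlog("estimate_b0: ", sum(is.na(centers)),
         " centroid fit(s) failed; their voxels are flagged")
  }
  delta_b0 <- centers[clusters$labels]
  flagged <- is.na(delta_b0) | abs(delta_b0) > threshold
  cluster_fits <- tibble::tibble(
    cluster = seq_len(k),
    amplitude = vapply(fits, function(f) f$amplitude, 1),
    fwhm = vapply(fits, function(f) f$fwhm, 1),
    center = vapply(fits, function(f) f$center, 1),
    rss = vapply(fits, function(f) f$rss, 1),
    converged = vapply(fits, function(f) f$converged, TRUE))
  structure(list(delta_b0 = delta_b0, flagged = flagged,
                 voxels = clusters$voxels, threshold = threshold,
                 cluster_fits = cluster_fits, dim3 = clusters$dim3,
                 spacing = clusters$spacing, frame_id = clusters$frame_id),
            class = "b0_map")
}

#' @export
print.b0_map <- function(x, ...) {
  cat("<b0_map> ", length(x$voxels), " voxels, ", sum(x$flagged),
      " flagged (|dB0| > ", x$threshold, " ppm)\n", sep = "")
  print(x$cluster_fits)
  invisible(x)
}

# Cubic-spline resampling of spectra onto a shifted offset axis, expressed as
# a linear operator on the sampled values: all voxels sharing one DeltaB0 are
# corrected with a single matrix multiply. xout beyond the sampled range is
# clamped to the nearest sample (no extrapolation).
shift_operator <- function(offsets, shift) {
  k <- length(offsets)
  xout <- offsets + shift
  xout <- pmin(pmax(xout, offsets[1]), offsets[k])
  M <- matrix(0, k, k)
  for (j in seq_len(k)) {
    e <- numeric(k); e[j] <- 1
    M[, j] <- stats::spline(offsets, e, xout = xout, method = "natural")$y
  }
  M
}

#' Correct z-spectra for static-field offsets
#'
#' Re-interpolates each voxel's spectrum onto the nominal offset axis after
#' shifting the frequency axis by its -DeltaB0 (the corrected spectrum at
#' nominal offset `w` is the measured spectrum evaluated at `w + DeltaB0`),
#' using natural cubic splines. Offsets shifted beyond the sampled range are
#' clamped to the edge sample. Voxels without a DeltaB0 estimate pass through
#' unchanged.
#'
#' @param series A [zspectrum_series()].
#' @param b0 A [estimate_b0()] result on the same grid.
#' @return A corrected [zspectrum_series()].
#' @export
correct_b0 <- function(series, b0) {
  stopifnot(inherits(series, "zspectrum_series"), inherits(b0, "b0_map"))
  sm <- list(mat = series$signal, voxels = series$voxels, dim3 = series$dim3)
  rows <- if (is.null(sm$voxels)) b0$voxels else match(b0$voxels, sm$voxels)
  if (anyNA(rows)) stop("correct_b0: b0 map covers voxels absent from series")
  out <- series$signal
  shifts <- unique(b0$delta_b0[!is.na(b0$delta_b0)])
  for (s in shifts) {
    if (abs(s) < 1e-9) next
    vr <- rows[!is.na(b0$delta_b0) & b0$delta_b0 == s]
    M <- shift_operator(series$offsets_ppm, s)
    out[vr, ] <- series$signal[vr, , drop = FALSE] %*% t(M)
  }
  series$signal <- out
  series
}

# Linear operator evaluating a sampled spectrum at arbitrary offsets by
# natural cubic spline (shared across voxels).
interp_operator <- function(offsets, xout) {
  k <- length(offsets)
  M <- matrix(0, length(xout), k)
  for (j in seq_len(k)) {
    e <- numeric(k); e[j] <- 1
    M[, j] <- stats::spline(offsets, e, xout = xout, method = "natural")$y
  }
  M
}

#' MTR asymmetry at the amine resonance
#'
#' `MTR_asym = mean over w in [center - hw, center + hw] of
#' (S(-w) - S(+w)) / s0 * 100` (percent), i.e. the asymmetry at 3.0 ppm
#' integrated over a 0.4 ppm band with the default settings. Sampled offsets
#' inside the band are used directly; the matching negative-offset values are
#' spline-interpolated when the sampling is asymmetric. Voxels with
#' non-positive `s0` are masked.
#'
#' @param series A (B0-corrected) [zspectrum_series()].
#' @param band_center Band center in ppm (default 3.0).
#' @param band_halfwidth Band half-width in ppm (default 0.2).
#' @return An [image_volume()] of MTR_asym in percent (NA outside the series
#'   voxels and at masked voxels).
#' @export
compute_mtr_asym <- function(series, band_center = 3.0,
                             band_halfwidth = 0.2) {
  stopifnot(inherits(series, "zspectrum_series"))
  off <- series$offsets_ppm
  band <- off[off >= band_center - band_halfwidth - 1e-9 &
                off <= band_center + band_halfwidth + 1e-9]
  if (length(band) < 1) stop("compute_mtr_asym: no offsets in the band")
  # positive-side samples taken directly; negative side matched by
  # interpolation (exact when sampling is symmetric)
  Mpos <- interp_operator(off, band)
  Mneg <- interp_operator(off, -band)
  Spos <- series$signal %*% t(Mpos)
  Sneg <- series$signal %*% t(Mneg)
  mtr <- 100 * rowMeans(Sneg - Spos) / series$s0
  mtr[!is.finite(series$s0) | series$s0 <= 0] <- NA_real_
  values_to_volume(mtr, series$voxels,
                   series$dim3 %||% stop("series lacks grid dims"),
                   series$spacing, series$frame_id)
}

#' Lesion-level CEST quality gate
#'
#' A lesion's MTR_asym median is considered unreliable when more than
#' `max_flagged_frac` of its tumor voxels carry an excessive static-field
#' offset; such lesions are excluded from the CEST analysis (mirroring
#' per-lesion exclusions for field inhomogeneity).
#'
#' @param b0 A [estimate_b0()] result.
#' @param tumor Tumor [binary_mask()].
#' @param max_flagged_frac Maximum tolerated flagged fraction (default 0.25).
#' @return Logical: `TRUE` when the lesion's CEST measurement is valid.
#' @export
cest_lesion_valid <- function(b0, tumor, max_flagged_frac = 0.25) {
  stopifnot(inherits(b0, "b0_map"), inherits(tumor, "binary_mask"))
  tum_vox <- which(tumor$data)
  pos <- match(tum_vox, b0$voxels)
  pos <- pos[!is.na(pos)]
  if (length(pos) == 0) return(FALSE)
  mean(b0$flagged[pos]) <= max_flagged_frac
}
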