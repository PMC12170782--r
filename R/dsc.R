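#' Dynamic susceptibility contrast (DSC) time series
#'
#' @param signal 4D array `(x, y, z, t)` of magnitude signal (a.u.), or a
#'   voxel-by-frame matrix for a masked series (then `voxels` and `dim3` give
#'   the linear voxel indices and the 3D grid).
#' @param tr Repetition time in seconds.
#' @param te Echo time in seconds.
#' @param baseline_idx Integer indices of pre-bolus frames; `NULL` to detect
#'   automatically (see [detect_baseline()]).
#' @param spacing Voxel spacing in mm.
#' @param voxels,dim3 Masked-representation metadata (see above).
#' @param frame_id Common-grid identifier.
#' @return An object of class `dsc_series`.
#' @export
dsc_series <- function(signal, tr, te, baseline_idx = NULL,
                       spacing = c(1, 1, 1), voxels = NULL, dim3 = NULL,
                       frame_id = "common") {
  sm <- series_matrix(signal, voxels, dim3)
  if (ncol(sm$mat) < 10L) stop("dsc_series: need at least 10 time points")
  if (!is.numeric(te) || te <= 0) stop("dsc_series: te must be positive")
  if (!is.numeric(tr) || tr <= 0) stop("dsc_series: tr must be positive")
  if (!is.null(baseline_idx)) {
    baseline_idx <- as.integer(baseline_idx)
    if (length(baseline_idx) == 0) stop("dsc_series: empty baseline_idx")
  }
  structure(list(signal = sm$mat, voxels = sm$voxels, dim3 = sm$dim3,
                 tr = tr, te = te, baseline_idx = baseline_idx,
                 spacing = as.numeric(spacing), frame_id = frame_id,
                 time = (seq_len(ncol(sm$mat)) - 1) * tr),
            class = "dsc_series")
}

#' Detect the pre-bolus baseline window
#'
#' Provisionally treats the first `n0` frames as baseline, then returns all
#' frames before the first frame at which the curve deviates from the
#' provisional baseline mean by more than `k` baseline standard deviations.
#'
#' @param curve Numeric vector (whole-brain mean signal or Delta-R2* curve).
#' @param n0 Number of provisional baseline frames.
#' @param k Deviation threshold in baseline SDs.
#' @return Integer vector of baseline frame indices.
#' @export
detect_baseline <- function(curve, n0 = 5L, k = 5) {
  n0 <- min(n0, length(curve) - 1L)
  m <- mean(curve[1:n0])
  s <- stats::sd(curve[1:n0])
  if (!is.finite(s) || s == 0) s <- 1e-3 * max(abs(m), 1)
  dev <- abs(curve - m) > k * s
  arrival <- which(dev)[1]
  if (is.na(arrival) || arrival <= 2L) return(seq_len(max(n0, 2L)))
  seq_len(arrival - 1L)
}

#' Convert DSC signal to Delta-R2*
#'
#' `DeltaR2*(t) = -ln(S(t) / S_baseline) / TE` per voxel, with `S_baseline`
#' the mean over the pre-bolus frames. Voxels with a non-positive baseline
#' are masked to NaN.
#'
#' @param series A [dsc_series()].
#' @return A list of class `delta_r2star` with elements `curves`
#'   (voxel-by-frame matrix, 1/s), `time` (s), `baseline_idx`, plus the grid
#'   metadata of the input.
#' @export
signal_to_delta_r2star <- function(series) {
  stopifnot(inherits(series, "dsc_series"))
  bidx <- series$baseline_idx
  if (is.null(bidx)) {
    ref_sig <- colMeans(series$signal)
    bidx <- detect_baseline(ref_sig)
  }
  sb <- rowMeans(series$signal[, bidx, drop = FALSE])
  bad <- !(sb > 0) | !is.finite(sb)
  dr2s <- -log(series$signal / sb) / series$te
  if (any(bad)) dr2s[bad, ] <- NA_real_
  dr2s[!is.finite(dr2s)] <- NA_real_
  structure(list(curves = dr2s, time = series$time, baseline_idx = bidx,
                 voxels = series$voxels, dim3 = series$dim3,
                 spacing = series$spacing, frame_id = series$frame_id),
            class = "delta_r2star")
}

#' Exponential-efflux convolution of a reference curve
#'
#' Computes `c(t) = integral_0^t xbar(tau) * exp(-kep * (t - tau)) dtau` by a
#' trapezoid rule with exact exponential propagation between samples. This is
#' the leakage kernel of the bidirectional two-compartment model; `kep = 0`
#' reduces it to the running integral of the unidirectional correction.
#'
#' @param xbar Reference curve (numeric vector).
#' @param t Time axis in seconds (same length).
#' @param kep Efflux rate in 1/s, `>= 0`.
#' @return Numeric vector, same length as `xbar`.
#' @export
leakage_convolution <- function(xbar, t, kep) {
  stopifnot(length(xbar) == length(t), kep >= 0)
  n <- length(t)
  out <- numeric(n)
  for (i in 2:n) {
    dt <- t[i] - t[i - 1]
    e <- exp(-kep * dt)
    out[i] <- out[i - 1] * e + dt / 2 * (xbar[i] + e * xbar[i - 1])
  }
  out
}

#' Default efflux-rate grid for the leakage fit
#'
#' 21 rates from 0 to 0.1 1/s: zero (unidirectional limit) plus 20
#' logarithmically spaced positive rates.
#'
#' @return Numeric vector of length 21.
#' @export
default_kep_grid <- function() {
  c(0, exp(seq(log(2e-3), log(0.1), length.out = 20)))
}

#' Bidirectional leakage fit of a single Delta-R2* curve
#'
#' Fits `DeltaR2*_meas(t) = k1 * xbar(t) - k2 * conv(xbar, kep)(t)` where
#' `conv` is [leakage_convolution()]. For each candidate `kep` on the grid
#' the model is linear in `(k1, k2)` and solved by least squares; the grid
#' point with minimal residual sum of squares wins. This keeps the fit
#' deterministic and exactly reproducible.
#'
#' @param curve Measured Delta-R2* curve (1/s).
#' @param reference Non-enhancing whole-brain mean Delta-R2* curve `xbar(t)`.
#' @param t Shared time axis (s).
#' @param kep_grid Candidate efflux rates (1/s); see [default_kep_grid()].
#' @return An object of class `leakage_fit` with fields `k1`, `k2`, `kep`,
#'   `rss`.
#' @export
fit_bidirectional_leakage <- function(curve, reference, t,
                                      kep_grid = default_kep_grid()) {
  stopifnot(length(curve) == length(t), length(reference) == length(t))
  if (all(abs(reference) < 1e-12)) {
    stop("fit_bidirectional_leakage: degenerate (all-zero) reference curve")
  }
  fit <- fit_leakage_matrix(matrix(curve, nrow = 1), reference, t, kep_grid)
  structure(list(k1 = fit$k1[1], k2 = fit$k2[1], kep = fit$kep[1],
                 rss = fit$rss[1]),
            class = "leakage_fit")
}

#' @export
print.leakage_fit <- function(x, ...) {
  cat(sprintf("<leakage_fit> k1 = %.4g, k2 = %.4g 1/s, kep = %.4g 1/s, rss = %.3g\n",
              x$k1, x$k2, x$kep, x$rss))
  invisible(x)
}

# Vectorized leakage fit: Y is a voxel x frame matrix of measured curves
# (one row per voxel; a frame x voxel matrix is transposed on entry). For
# each kep the design X = [xbar, -conv] is shared by all voxels, so the
# normal equations solve every voxel at once; rss via the identity
# rss = sum(y^2) - sum(beta * X'y).
fit_leakage_matrix <- function(Y, xbar, t, kep_grid = default_kep_grid()) {
  if (ncol(Y) != length(t)) Y <- t(Y)
  stopifnot(ncol(Y) == length(t))
  nv <- nrow(Y)
  yy <- rowSums(Y^2)
  best_rss <- rep(Inf, nv)
  k1 <- k2 <- kep_best <- rep(NA_real_, nv)
  conv_int <- numeric(length(kep_grid))
  kep_idx <- rep(NA_integer_, nv)
  w <- trapz_weights(t)
  for (j in seq_along(kep_grid)) {
    cv <- leakage_convolution(xbar, t, kep_grid[j])
    conv_int[j] <- sum(w * cv)
    X <- cbind(xbar, -cv)
    XtX <- crossprod(X)
    XtY <- t(Y %*% X)  # 2 x voxels
    B <- tryCatch(solve(XtX, XtY), error = function(e) {
      # conv ~ 0 (e.g. xbar flat zero tail): collinear design; fit k1 only
      rbind(XtY[1, ] / XtX[1, 1], 0)
    })
    rss <- pmax(yy - colSums(B * XtY), 0)
    better <- rss < best_rss - 1e-12
    if (any(better)) {
      best_rss[better] <- rss[better]
      k1[better] <- B[1, better]
      k2[better] <- B[2, better]
      kep_best[better] <- kep_grid[j]
      kep_idx[better] <- j
    }
  }
  list(k1 = k1, k2 = k2, kep = kep_best, kep_idx = kep_idx, rss = best_rss,
       conv_integral = conv_int)
}

#' Leakage-corrected, brain-median-normalized rCBV map
#'
#' Pipeline: (1) convert the signal series to Delta-R2*; (2) form the
#' reference curve `xbar(t)` as the mean Delta-R2* over non-enhancing brain
#' voxels (brain-mask voxels whose deltaT1 is at or below the brain median
#' when a deltaT1 map is supplied, optionally also excluding the tumor mask);
#' (3) fit the bidirectional leakage model per voxel; (4) integrate the
#' corrected curve `DeltaR2*_meas + k2 * conv` (equal to `k1 * xbar` at a
#' perfect fit) by the trapezoid rule over the full acquisition; (5) divide
#' by the median over the brain mask, so the output rCBV map has brain
#' median exactly 1.
#'
#' @param series A [dsc_series()].
#' @param brain Whole-brain [binary_mask()].
#' @param deltat1 Optional deltaT1 [image_volume()] used to restrict the
#'   reference curve to non-enhancing tissue.
#' @param tumor Optional tumor [binary_mask()] excluded from the reference.
#' @param kep_grid Efflux-rate grid for the per-voxel leakage fit.
#' @return An [image_volume()] of normalized rCBV (NA outside the brain),
#'   with the per-voxel fit summary attached as attribute `"fits"`.
#' @export
compute_rcbv <- function(series, brain, deltat1 = NULL, tumor = NULL,
                         kep_grid = default_kep_grid()) {
  stopifnot(inherits(series, "dsc_series"), inherits(brain, "binary_mask"))
  dr2s <- signal_to_delta_r2star(series)
  sm <- list(mat = dr2s$curves, voxels = dr2s$voxels, dim3 = dr2s$dim3)
  sel <- mask_rows(sm, brain)
  Y <- dr2s$curves[sel$rows, , drop = FALSE]  # voxels x frames
  ok <- rowSums(!is.finite(Y)) == 0
  # reference: non-enhancing brain voxels
  ref_keep <- ok
  if (!is.null(tumor)) {
    ref_keep <- ref_keep & !(sel$voxels %in% which(tumor$data))
  }
  if (!is.null(deltat1)) {
    dt1 <- deltat1$data[sel$voxels]
    med <- stats::median(dt1[ref_keep], na.rm = TRUE)
    ref_keep <- ref_keep & is.finite(dt1) & dt1 <= med
  }
  if (!any(ref_keep)) stop("compute_rcbv: no reference voxels available")
  xbar <- colMeans(Y[ref_keep, , drop = FALSE])
  fit <- fit_leakage_matrix(Y[ok, , drop = FALSE], xbar, dr2s$time, kep_grid)
  w <- trapz_weights(dr2s$time)
  raw_int <- as.numeric(Y[ok, , drop = FALSE] %*% w)
  corr_int <- raw_int + fit$k2 * fit$conv_integral[fit$kep_idx]
  rcbv <- rep(NA_real_, length(sel$rows))
  rcbv[ok] <- corr_int
  med_brain <- stats::median(rcbv, na.rm = TRUE)
  if (!is.finite(med_brain) || med_brain <= 0) {
    stop("compute_rcbv: non-positive brain-median rCBV; cannot normalize")
  }
  rcbv <- rcbv / med_brain
  out <- values_to_volume(rcbv, sel$voxels, sm$dim3 %||% dim(brain$data),
                          series$spacing, series$frame_id)
  attr(out, "fits") <- tibble::tibble(
    voxel = sel$voxels[ok], k1 = fit$k1, k2 = fit$k2, kep = fit$kep,
    rss = fit$rss)
  out
}
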