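#' Two-b-value diffusion-weighted image pair
#'
#' Container for the b = 0 and b = 1000 s/mm^2 signal volumes used to compute
#' the apparent diffusion coefficient map.
#'
#' @param s_b0,s_b1000 [image_volume()]s of the low- and high-b signals (a.u.).
#' @param b_low,b_high Diffusion weightings in s/mm^2; `b_high > b_low >= 0`.
#' @return An object of class `dwi_pair`.
#' @export
dwi_pair <- function(s_b0, s_b1000, b_low = 0, b_high = 1000) {
  assert_same_grid(s_b0, s_b1000, "DWI signal volumes")
  if (!(b_high > b_low && b_low >= 0)) {
    stop("dwi_pair: need b_high > b_low >= 0")
  }
  structure(list(s_b0 = s_b0, s_b1000 = s_b1000,
                 b_low = b_low, b_high = b_high),
            class = "dwi_pair")
}

# Vector core of the ADC computation; exposed internally so the cohort engine
# can run on masked voxel vectors without building full volumes.
adc_from_signals <- function(s0, s1, b_low, b_high) {
  if (b_high == b_low) stop("ADC: b values must differ")
  ok <- is.finite(s0) & is.finite(s1) & s0 > 0 & s1 > 0 & s1 <= s0
  adc <- rep(NA_real_, length(s0))
  adc[ok] <- log(s0[ok] / s1[ok]) / (b_high - b_low) * 1e6  # mm^2/s -> um^2/s
  adc
}

#' Apparent diffusion coefficient map
#'
#' Computes the per-voxel ADC in um^2/s from a two-b-value DWI pair as
#' `ADC = ln(S_b0 / S_b1000) / (b_high - b_low) * 1e6`. Voxels with a
#' non-positive signal, or where the high-b signal exceeds the low-b signal
#' (negative apparent diffusivity), are set to NaN rather than clamped so that
#' ROI medians remain honest.
#'
#' @param pair A [dwi_pair()].
#' @return An [image_volume()] of ADC in um^2/s with NA at invalid voxels.
#' @examples
#' s0 <- image_volume(array(1000, c(4, 4, 4)))
#' s1 <- image_volume(array(1000 * exp(-1), c(4, 4, 4)))
#' adc <- compute_adc(dwi_pair(s0, s1))
#' adc$data[1, 1, 1]  # 1000 um^2/s
#' @export
compute_adc <- function(pair) {
  stopifnot(inherits(pair, "dwi_pair"))
  adc <- adc_from_signals(as.numeric(pair$s_b0$data),
                          as.numeric(pair$s_b1000$data),
                          pair$b_low, pair$b_high)
  image_volume(array(adc, dim(pair$s_b0$data)),
               spacing = pair$s_b0$spacing, frame_id = pair$s_b0$frame_id)
}

#' Inputs for the T1-weighted subtraction map
#'
#' @param t1w_pre,t1w_post Pre- and post-contrast T1-weighted
#'   [image_volume()]s (a.u.).
#' @param brain Whole-brain [binary_mask()] used for intensity normalization.
#' @return An object of class `delta_t1_inputs`.
#' @export
delta_t1_inputs <- function(t1w_pre, t1w_post, brain) {
  assert_same_grid(t1w_pre, t1w_post, "T1w volumes")
  assert_same_grid(t1w_pre, brain, "T1w volume and brain mask")
  if (!any(brain$data)) stop("delta_t1_inputs: brain mask is empty")
  structure(list(t1w_pre = t1w_pre, t1w_post = t1w_post, brain = brain),
            class = "delta_t1_inputs")
}

#' T1-weighted subtraction (deltaT1) map
#'
#' Each image is first scaled so that its median intensity inside the brain
#' mask equals 1 (a scale-free normalization making the subtraction robust to
#' arbitrary scanner gain), then deltaT1 = post - pre. Positive values reflect
#' contrast enhancement and serve as a semiquantitative proxy of blood-brain
#' barrier permeability. A pure global rescaling of either input leaves the
#' result unchanged.
#'
#' @param inp A [delta_t1_inputs()].
#' @return An [image_volume()] of deltaT1 in normalized units.
#' @export
compute_delta_t1 <- function(inp) {
  stopifnot(inherits(inp, "delta_t1_inputs"))
  med_pre <- stats::median(inp$t1w_pre$data[inp$brain$data], na.rm = TRUE)
  med_post <- stats::median(inp$t1w_post$data[inp$brain$data], na.rm = TRUE)
  if (!is.finite(med_pre) || med_pre == 0 || !is.finite(med_post) ||
      med_post == 0) {
    stop("compute_delta_t1: zero or undefined brain-median intensity")
  }
  delta <- inp$t1w_post$data / med_post - inp$t1w_pre$data / med_pre
  image_volume(delta, spacing = inp$t1w_pre$spacing,
               frame_id = inp$t1w_pre$frame_id)
}
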