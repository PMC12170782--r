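---
title: "Methods: multiparametric MRI quantification and diffusion phenotyping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multiparametric MRI quantification and diffusion phenotyping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gbmphen)
```

## The problem

Post-chemoradiation glioblastomas can be stratified into two diffusion MRI
phenotypes by the ADC_L statistic — the mean of the lower component of a
two-Gaussian model fit to the apparent diffusion coefficient (ADC) histogram
inside the contrast-enhancing tumor — with an externally validated cutoff of
1240 µm²/s (high-ADC_L: ADC_L ≥ 1240; low-ADC_L: ADC_L < 1240). The high
phenotype is the one previously associated with a favorable response to
anti-VEGF therapy. `gbmphen` implements the quantitative maps needed to
characterize these phenotypes (ADC, leakage-corrected rCBV, amine CEST
MTR_asym at 3 ppm, SAGE qT2/qT2*, deltaT1), the per-lesion phenotyping, the
cohort-level statistics, and a signal-level synthetic cohort generator that
makes every stage verifiable without patient data.

All volumes are assumed co-registered to one common grid; the package
enforces an exact shape/spacing/frame match and performs no resampling,
registration or segmentation (masks are inputs).

## Per-voxel quantification

### ADC

From a two-b-value DWI pair, `ADC = ln(S_b0 / S_b1000) / (b_high − b_low)`,
reported in µm²/s (default b = 0 and 1000 s/mm²). Voxels with non-positive
signals, or with `S_b1000 > S_b0` (negative apparent diffusivity), are set
to NaN rather than clamped, so that ROI medians are never contaminated by
truncation.

### deltaT1

Pre- and post-contrast T1-weighted images are each scaled so their median
intensity inside the brain mask equals 1, then subtracted (post − pre). The
brain-median normalization is a deliberate, scale-free choice: it removes
arbitrary scanner gain from both inputs, making the map invariant to
independent global rescaling, while remaining a semiquantitative measure of
contrast enhancement.

### DSC rCBV with bidirectional leakage correction

The signal series is converted to `ΔR2*(t) = −ln(S(t)/S̄_baseline)/TE`. The
pre-bolus baseline window is taken from the series metadata when present,
otherwise detected as the frames preceding the first deviation of the
whole-brain mean curve beyond 5 baseline standard deviations.

Contrast extravasation is modelled with a two-compartment bidirectional
exchange term:

    ΔR2*_meas(t) = k1·x̄(t) − k2·∫₀ᵗ x̄(τ)·e^(−kep·(t−τ)) dτ

where `x̄(t)` is the mean ΔR2* of non-enhancing brain (brain-mask voxels at
or below the median deltaT1, tumor excluded). For each candidate efflux rate
`kep` on a fixed grid — 0 (the unidirectional limit) plus 20 logarithmically
spaced rates up to 0.1 s⁻¹ — the model is linear in `(k1, k2)` and solved by
least squares; the grid point with minimal residual wins. The grid-search
linearization keeps the fit deterministic, exactly reproducible and cheap to
vectorize over hundreds of thousands of voxels (a shared design matrix per
grid point solves every voxel at once). The corrected curve
`ΔR2*_meas + k2·conv` is integrated by the trapezoid rule over the full
acquisition (no gamma-variate re-fit), and the map is divided by its brain
median, so the output has brain-median 1 by construction.

### Amine CEST MTR_asym at 3 ppm with B0 correction

Spectra are normalized by the unsaturated reference S0, grouped by k-means
on the spectrum vectors (default 4 clusters, seeded; centroids estimated on
a 20 000-voxel subsample when the mask is larger, then all voxels assigned
to the nearest centroid), and each centroid is fit over |ω| ≤ 1.5 ppm with a
single-pool Lorentzian

    L(ω) = 1 − A·(Γ/2)² / ((Γ/2)² + (ω − ΔB0)²)

whose center is the cluster's static-field offset ΔB0. Every voxel inherits
its cluster's ΔB0 (no per-voxel refinement); voxels with |ΔB0| > 0.3 ppm
are flagged, and a lesion whose tumor mask is more than 25% flagged is
excluded from the CEST analysis. The 25% fraction is this package's
operationalization of a per-lesion artifact exclusion; only the 0.3 ppm
voxel threshold is externally specified.

Correction re-evaluates each spectrum at `ω + ΔB0` by natural cubic splines.
Because the shift is constant within a cluster, the interpolation is a
per-cluster linear operator (a small matrix applied to all of the cluster's
voxels), which makes the correction exact to spline tolerance and fast.
Offsets shifted beyond the sampled range are clamped to the edge sample.

`MTR_asym = mean over ω ∈ [2.8, 3.2] ppm of (S(−ω) − S(+ω))/S0 × 100` (%).
Band integration is the arithmetic mean over the sampled offsets in the
band; with the dense symmetric sampling the package expects, this is
equivalent to a trapezoid over ppm to first order.

The cluster-constant ΔB0 is the main approximation: on smooth synthetic
fields it leaves a per-lesion residual of up to about ±2% (relative) in the
tumor MTR_asym median, with no systematic sign across lesions. Increasing
the cluster count reduces it; 4 clusters is the default because the
correction scheme this emulates does not pin the count.

### SAGE qT2 / qT2*

The four SAGE reference echoes (two gradient echoes, one mixed echo, one
spin echo) follow the piecewise signal equations

    gradient regime:  S(τ) = S0_I · e^(−τ·R2*)
    spin regime:      S(τ) = S0_II · e^(−TE_SE·(R2*−R2)) · e^(−τ·(2R2−R2*))

The mixed echo is treated as a spin-regime sample at τ₃ < TE_SE. With four
echoes and four unknowns the system is exactly determined, so the closed
form — `R2*` from the gradient pair, `2R2 − R2*` from the spin pair — is
the least-squares solution and is the default; a per-voxel nonlinear polish
is available but cannot reduce the residual further on four echoes. Default
echo times (14, 34, 60, 92) ms with TE_SE = 92 ms are representative
SAGE-EPI values and are configurable. Voxels with non-positive signals or
rates are invalid (NaN); `qT2* > qT2` is physically implausible but only
flagged, never silently repaired.

## Phenotyping

Tumor ADC values are binned into a density-normalized histogram (50 µm²/s
bins over 0–4000 µm²/s) and fit with a two-Gaussian mixture by bounded
nonlinear least squares, initialized at the 25th/75th percentiles, with
`mu_lo ≤ mu_hi` enforced by swap. If the components collapse (separation
< 100 µm²/s or a weight below 0.02) a single Gaussian is refit and its mean
taken as ADC_L. Bin width, range and the collapse thresholds are package
choices; tests assert the histogram fit agrees with an
expectation-maximization fit (the `method = "em"` cross-check) to within
30 µm²/s on well-separated mixtures. Classification is boundary-inclusive:
ADC_L = 1240 µm²/s is high.

RANO measurability is operationalized as the tumor bounding box spanning at
least 10 mm on all three axes — a simplification of the orthogonal-diameter
rule that is exact for the ellipsoidal lesions the generator produces.

## Cohort statistics

Group differences in the six MRI metrics (CE volume, median deltaT1, rCBV,
MTR_asym, qT2, qT2*) use two-sided Mann-Whitney U tests — exact enumeration
when both groups have ≤ 8 observations without ties, otherwise the normal
approximation with tie and continuity correction — and form one
Benjamini-Hochberg family; the five location tests (one-vs-rest Fisher's
exact, point-probability two-sided convention) form another. Sex, MGMT and
EGFR are Fisher tests on 2×2 tables with unknowns excluded. MTR_asym is
additionally tested by OLS `mtr ~ phenotype + qT2`, since amine CEST
contrast carries a tissue-T2 dependence. Missing relaxometry (the SAGE
subset) is handled by per-analysis complete cases, never imputation.
Shapiro-Wilk normality is logged per metric and group but never branches
the analysis: group tests are always nonparametric.

k-means phenotype clustering standardizes ADC_L (continuous, not
dichotomized), median rCBV and median MTR_asym, runs k = 2 with 50 restarts
under a fixed seed, relabels so cluster 1 has the higher mean ADC_L, and
reports concordance with the cutoff grouping.

## The synthetic cohort generator

`cohort_config()` defaults define the emulated study conditions: 87 lesions
(37 high / 50 low ADC_L) on a 96³ grid at 1 mm isotropic spacing with an
ellipsoidal brain (semi-axes 40/44/36 mm); per-group two-Gaussian ADC
mixtures whose lower means sit at least 100 µm²/s from the 1240 cutoff;
per-group target ROI medians rCBV 1.02/1.28, MTR_asym 2.36/2.10%, qT2
114.8/100.9 ms; log-normal CE volumes with medians 21.4/16.4 cc (spreads
solved from the corresponding interquartile ranges, ranks truncated to
[0.05, 0.95] and volumes capped at 60 cc so lesions fit the synthetic
brain); location, sex, MGMT and EGFR counts allocated deterministically and
shuffled by seed; a 68-lesion relaxometry subset (29/39); qT2* and deltaT1
with no group difference, serving as negative controls.

Two design choices deserve emphasis:

* **Quantile-stratified sampling.** Per-lesion continuous targets are drawn
  at stratified mid-ranks of the group distribution and then shuffled, so
  the sample median of each group equals the configured median at any seed;
  categorical covariates are exact counts. This mirrors what the generator
  is for — reproducing a fixed, printed cohort structure — rather than
  resampling a hypothetical population. `sampling = "random"` restores
  plain draws; the `null = TRUE` preset (no group differences) uses random
  sampling, because a quantile-matched null cohort would make the two
  groups identical and type-I calibration meaningless.
* **Normalization-aware rCBV truth.** The tumor is part of the brain, so
  whole-brain-median normalization sees the tumor's values. The generator
  calibrates the brain field so that the tumor ROI median equals its target
  *after* normalization; without this the low-ADC_L group would be biased
  low by a few percent purely by construction.

Forward models are the exact inverses of the analysis stages plus noise:
DWI signal decay; a gamma-variate bolus with the bidirectional leakage term
(one `kep` per lesion, voxelwise `k2` amplitude, `kep` drawn continuously,
not snapped to the fit grid); two-pool Lorentzian z-spectra (water at the
local ΔB0, amine at ΔB0 + 3 ppm, amplitude solved linearly so the corrected
band-integrated asymmetry equals the target) over a smooth low-order
polynomial ΔB0 field; the piecewise SAGE equations. Noise is additive
Gaussian on magnitude signals at per-modality SNRs (DWI 40, DSC 60, CEST
80, SAGE 100, T1w 60) — a Rician-regime approximation valid at these SNRs.
Saturation physics, anatomy, motion and scanner artifacts are *not*
simulated: passing tests demonstrate the correctness and calibration of the
estimators under the stated models, not robustness to every property of
real data.

4D series use a masked voxel-by-frame representation restricted to the
brain, so a full 87-lesion signal-level run (~265 000 brain voxels per
lesion, 40 DSC frames, 25 CEST offsets, 4 echoes) completes in minutes on
one CPU; dense 4D NIfTI import/export is supported for on-disk bundles.

## Numerical choices and degenerate inputs

* kep grid: 21 deterministic points, 0 plus log-spaced (0.002–0.1 s⁻¹);
  collinear designs (flat convolution) fall back to a k1-only fit.
* Histogram fit: bounded Levenberg-Marquardt (`minpack.lm`), weights
  parameterized as `w` and `1 − w`; failed fits fall back to a
  single-Gaussian description flagged `collapsed_to_single`.
* Lorentzian centroid fits bounded to |center| ≤ 1 ppm; non-convergent
  centroids flag their voxels rather than guessing.
* k-means (both uses) runs under a locally-seeded RNG that is restored
  afterwards, so library calls never perturb the caller's random stream.
* Empty masks warn and return empty/false; all-identical group values give
  p = 1 with a warning; zero-variance covariates are dropped with a
  warning; a corrupt lesion bundle becomes a logged exclusion, not an
  abort.

## Problem sizes used by the test suite

The acceptance suite runs the full signal-level default cohort once (87
lesions, 96³ grid), 200 double-Gaussian recovery ROIs at 20 000 values
each, 200 null cohorts for type-I calibration at the ground-truth table
level (the battery consumes lesion-level medians, so image simulation adds
nothing to that check), and 20 clustering seeds. These sizes were chosen as
the smallest that pin each property tightly.

## Known limitations

* Cluster-constant ΔB0 leaves per-lesion MTR_asym residuals of up to ~±2%
  on smooth fields (see above).
* The generator's lesions are ellipsoids on a homogeneous brain; location
  labels are covariates, not geometry, and frequency maps on synthetic
  cohorts reflect placement randomness only.
* The leakage model shares the measured reference curve between simulation
  and fitting; recovery tests therefore validate the estimator, not bolus
  physiology.
* Survival analysis and anything upstream of co-registered volumes
  (registration, motion correction, skull stripping, segmentation) are out
  of scope.
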