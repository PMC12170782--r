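# gbmphen

Multiparametric MRI quantification and diffusion phenotyping of
post-chemoradiation glioblastoma.

## What it does, and for whom

Post-chemoradiation glioblastomas separate into two diffusion MRI phenotypes
by **ADC_L** — the mean of the lower component of a two-Gaussian model fit to
the apparent diffusion coefficient (ADC) histogram inside the
contrast-enhancing tumor — with a validated cutoff of **1240 µm²/s**
(high-ADC_L: ADC_L ≥ 1240, the phenotype associated with favorable anti-VEGF
response; low-ADC_L otherwise). `gbmphen` is for imaging scientists who want
to reproduce or extend this kind of multiparametric characterization: it
computes the quantitative maps, phenotypes each lesion, runs the cohort-level
statistics, and ships a signal-level synthetic cohort generator so every
stage can be verified end-to-end without patient data.

The quantitative core, per lesion (all volumes co-registered NIfTI on one
grid; masks are inputs):

* **ADC** (µm²/s) from a two-b-value DWI pair:
  `ADC = ln(S_b0/S_b1000)/(b_high − b_low)`.
* **rCBV** from DSC perfusion: `ΔR2*(t) = −ln(S(t)/S̄_baseline)/TE`, fit with
  the bidirectional leakage model
  `ΔR2*_meas(t) = k1·x̄(t) − k2·∫ x̄(τ)·e^(−kep(t−τ))dτ` (linear grid search
  over kep), corrected, integrated, and normalized to the whole-brain median.
* **MTR_asym @ 3 ppm** (%) from amine CEST z-spectra: k-means clustering of
  spectra + Lorentzian fitting estimates the static-field offset ΔB0 per
  voxel, spectra are re-interpolated, voxels with |ΔB0| > 0.3 ppm flagged,
  and `MTR_asym = mean_{ω∈[2.8,3.2]} (S(−ω) − S(+ω))/S0 × 100`.
* **qT2 / qT2*** (ms) from the 4-echo SAGE reference images via the piecewise
  gradient/spin-echo equations, solved in closed form.
* **deltaT1** from brain-median-normalized post- minus pre-contrast T1w.

Cohort analysis: Mann-Whitney U group tests with Benjamini-Hochberg
correction, Fisher's exact tests (locations, sex, MGMT, EGFR), a
qT2-adjusted regression of MTR_asym, Pearson correlations, and k-means
phenotype clustering (k = 2) on ADC_L, rCBV and MTR_asym with concordance
against the cutoff grouping.

## Worked example

Generate the default synthetic cohort's ground-truth lesion table (87
lesions, 37 high / 50 low ADC_L, covariate counts fixed) and run the full
statistical battery:

```r
library(gbmphen)
cohort <- ground_truth_profiles(generate_cohort_table(cohort_config()))
report <- analyze_cohort(cohort, seed = 42)
report
```

```
<cohort_report> 87 lesions

Group comparisons:
# A tibble: 7 × 10
  metric          n_high n_low median_high median_low u_stat     p_raw    p_adj
1 volume_cc           37    50       21.4       16.4   1116. 0.101     0.152
2 median_deltat1      37    50        0.5        0.5    925  1         1
3 median_rcbv         37    50        1.02       1.28   466  0.0000827 0.000248
4 median_mtr_asym     37    50        2.36       2.1   1228  0.00940   0.0188
5 median_qt2          29    39      115.       101.     890  0.0000588 0.000248
6 median_qt2star      29    39       56.3       55.2    607  0.611     0.733
7 steroid_dose_mg     37    50        0          0      884. 0.705     0.705

Location tests (Fisher, BH family of 5):
  frontal  7/37 vs 22/50  p = 0.0209 → adjusted 0.104 (not significant)
  temporal 13/37 vs  8/50 p = 0.0464 → adjusted 0.116 (not significant)
  ...

<phenotype_clusters> k = 2 on (adc_l, median_rcbv, median_mtr_asym):
  concordance 0.977 (2 discordant of 87)
```

Reading it: the high-ADC_L group shows lower median rCBV (1.02 vs 1.28),
higher MTR_asym (2.36% vs 2.10%) and longer qT2 (115 vs 101 ms); volume,
deltaT1, qT2* and steroid dose do not differ; the two nominally significant
location tests do not survive BH correction; and unsupervised k = 2
clustering on the continuous metrics almost perfectly recovers the 1240
µm²/s split.

The same table can be produced the long way — simulating raw DWI/DSC/CEST/
SAGE/T1w signals per lesion and quantifying them:

```r
run <- run_synthetic_cohort(cohort_config())   # ~10 min on one CPU
analyze_cohort(run$cohort, seed = 42)
```

Per-lesion pieces are exposed individually (`compute_adc()`,
`compute_rcbv()`, `cluster_zspectra()` / `estimate_b0()` / `correct_b0()` /
`compute_mtr_asym()`, `solve_sage()`, `fit_adc_double_gaussian()`,
`extract_lesion_profile()`), return tibbles or tidy-able objects
(`tidy()`, `glance()`, `autoplot()`), and read/write NIfTI via
`read_volume()` / `write_volume()` and the bundle helpers. A thin CLI
wrapper lives at `inst/scripts/gbmphen.R`
(`simulate | run | stats` subcommands).

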