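---
title: "Seed-based resting-state connectivity and aging: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seed-based resting-state connectivity and aging: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stnfc)
```

## The analysis

`stnfc` implements a seed-based resting-state functional-connectivity
(FC) aging analysis for a small bilateral seed region — the subthalamic
nucleus (STN), a basal-ganglia structure central to motor response
control. The question the pipeline answers is: *which brain regions'
spontaneous BOLD fluctuations couple (or anticorrelate) with the seed,
and how does that coupling change across adulthood?*

The processing chain, per subject:

1. **Volume discard.** The first 4 volumes are dropped (T1 saturation).
2. **Spatial smoothing.** Separable Gaussian, 5 mm FWHM; per-axis sigma
   in voxels is `fwhm / (sqrt(8 ln 2) * voxel_size)`.
3. **Nuisance regression.** Each voxel series is replaced by its
   least-squares residual against 16 regressors: an intercept, the six
   realignment (motion) parameters, their backward differences, and the
   spatial mean series of the gray-matter, white-matter and CSF
   compartments. This guards the age analysis against the well-known
   age–motion correlation.
4. **Band-pass 0.01–0.08 Hz.** An ideal discrete-Fourier filter: the
   Fourier coefficients inside the band are kept exactly, everything
   else — including DC — is zeroed.
5. **Seed series.** The seed's representative time series is its *first
   eigenvariate*: the first left singular vector of the centered
   time × voxel matrix of seed voxels, rescaled to unit variance and
   sign-aligned with the spatial mean. For the main analysis the left
   and right seed ROIs are collapsed into one bilateral seed by taking
   the eigenvariate of the voxel union; per-hemisphere seeds support
   the supplementary lateralization analyses.
6. **FC map.** Pearson correlation of the seed series with every
   gray-matter voxel, Fisher-Z transformed (`z = atanh(r)`, |r| clipped
   at 1 − 1e-7).

At the group level, the per-subject Z-maps enter a voxel-wise linear
model with an intercept and centered covariates: age (years), sex
(±0.5), and site (effect-coded, so the intercept estimates the
covariate-adjusted mean FC). Age effects are tested *in conjunction*
with the matching FC main effect: e.g. an age-related decrease of
positive FC requires, at every voxel, one-sided `t_main > t_crit` AND
`t_age < −t_crit` at the voxel-forming threshold p < 0.001. Surviving
voxels are clustered (26-connectivity by default) and cluster extent is
tested at family-wise error (FWE) p < 0.05, with an exploratory liberal
threshold of p < 0.1 reported separately.

### Permutation FWE instead of random-field theory

Classical SPM-style cluster correction derives the null distribution of
cluster extent from random-field theory and an estimated smoothness.
This package instead uses a **Freedman–Lane permutation scheme** on the
age covariate: fit the reduced model (all covariates except age),
permute its residuals, refit the full model, re-threshold the age
t-map, intersect it with the *fixed* observed main-effect pass set, and
record the maximum cluster size. The observed clusters' corrected
p-values use the add-one estimator
`p_fwe = (1 + #(perm max >= size)) / (1 + n_perm)`, so p-values are
never zero and never below `1/(n_perm+1)`. This choice is deliberate:
permutation needs no smoothness machinery, makes minimal distributional
assumptions, and — crucially — its error control can be *measured* on
simulated null cohorts (see `fwe_calibration()`). Holding the
main-effect mask fixed is coherent because the conjunction's
inferential target is the age effect; permuting age cannot disturb a
main effect it does not enter.

### Per-cluster aging statistics

For every surviving cluster the package reports the quantities a reader
expects next to such a map:

* split-half mean coupling: subjects are sorted by age (ties broken by
  subject id), the lower and upper `floor(N/2)` form the *younger* and
  *older* groups (the median subject is excluded when N is odd — 361
  subjects give exactly 180/180), and each group's mean r is the
  back-transformed mean Fisher-Z;
* a Welch two-sample t on the subject-level Fisher-Z values, computed
  as younger − older so a *positive* t means coupling declines with
  age (matching the sign convention of the split-half tables this
  mirrors);
* the Spearman rank correlation of coupling with age over all subjects;
* a small-effect filter: clusters are only reported when |mean r| > 0.1
  (strictly) in the younger group, the older group, or both.

The subject-level cluster coupling is the mean Fisher-Z over cluster
voxels, back-transformed (`cluster_fc_mode = "mean_z"`); correlating
the cluster-mean *time series* with the seed is a defensible
alternative reading, but mean-Z is linear in the quantities the group
GLM models, so the cluster statistics stay consistent with the
inference that selected the cluster.

### Hemispheric analyses

`hemispheric_analysis()` tests lateralization by feeding the paired
difference `D = Z_left − Z_right` through the same covariate-adjusted
GLM and conjunction/permutation machinery.
`interhemispheric_fc_vs_age()` correlates the left and right seed
eigenvariates per subject and summarizes the age dependence of that
interhemispheric coupling with the same split-half/Welch/Spearman
statistics.

## The synthetic cohort generator

No imaging data ships with the package; the original study's scans are
not public. Every downstream stage is instead exercised on a synthetic
multi-site cohort (`simulation_config()`, `simulate_cohort()`) whose
*statistical* structure matches what the analysis assumes. The
generator is a stand-in, not a biophysical model; its choices are:

* **Cohort make-up.** 361 subjects by default, ages uniform 18–85,
  34.5% female, three sites assigned round-robin; TR 2.2 s, 250
  volumes, 3 mm isotropic voxels. These mirror the multi-site aging
  cohort the pipeline is designed for.
* **Geometry.** A compact 16³ grid with disjoint *cuboid* regions:
  2×2×2 left/right seed ROIs, 3³ WM and CSF compartments, 3³ effect
  regions, gray-matter background elsewhere. Cuboids give exact voxel
  counts for cluster tests; nothing anatomical is claimed.
* **Signals.** All latents are Gaussian white noise band-passed to
  0.01–0.08 Hz and standardized, so planted couplings survive the
  pipeline's own filter and ground truth stays interpretable after
  preprocessing. Left and right seed latents share an age-dependent
  interhemispheric correlation (default 0.43 at the mean age,
  +0.0019/yr, the magnitude of the interhemispheric aging effect the
  pipeline should recover). An effect region with specification
  `(baseline_r, age_slope)` carries
  `rho * s + sqrt(1 − rho²) * eps_region` with
  `rho = baseline_r + age_slope * (age − mean_age)`; negative `rho`
  plants anticorrelation. Default effects mirror the kinds of findings
  the method targets: a strong stable coupling (r = 0.40), a declining
  one (0.13 at mean age, −0.002/yr — insula-like magnitudes), an
  increasing one (0.08, +0.002/yr), and a strengthening anticorrelation
  (−0.08, −0.002/yr).
* **Nuisance structure.** Per-voxel white noise (SD 1 relative to the
  unit-variance latents); a site-specific mean offset (SD 5); a linear
  drift; six random-walk motion traces mixed into every voxel with
  random weights (so the motion regressors can actually remove the
  contamination, and so can be validated); and global WM/CSF signals
  added to every voxel (so the tissue-mean regressors have work to do).
* **Determinism.** Every random stream is derived from the root seed
  and a stable string hash (stage, subject id), so cohorts are
  bit-reproducible and independent of subject processing order.

What the generator does *not* emulate: hemodynamic response shapes,
cardiac/respiratory physiology, motion spike artifacts, spatial
autocorrelation of real BOLD noise, anatomical geometry, or
registration error. Passing tests therefore demonstrate that the
*statistical machinery* is correct and calibrated under the stated
model — not that the pipeline is robust to everything real data can do.

## Numerical choices

* Fisher-Z clipping at |r| = 1 − 1e-7 keeps self-correlation finite
  (z ≈ 8.39).
* Zero-variance voxels get z = 0 and leave the analysis mask.
* Degenerate zero-residual GLM fits cap |t| at 1e6.
* The eigenvariate sign tie-break (spatial-mean correlation exactly 0)
  forces the first nonzero element positive, for determinism. The
  eigenvariate is unit-variance; other scalings would not change any
  correlation downstream.
* Smoothing uses half-sample reflect padding, which preserves local
  means near the edges of small synthetic grids; kernels are truncated
  at 4 sigma and renormalized to unit mass.
* The ideal band-pass is realized as projection onto the orthonormal
  cosine/sine basis of the in-band DFT bins — algebraically identical
  to zeroing FFT coefficients, verified against an FFT oracle in the
  tests. Applying it twice equals applying it once (it is a
  projection).
* Nuisance regressors are not themselves band-passed; filtering follows
  regression, in the order the preprocessing chain states. The chain
  order (discard → smooth → residualize → band-pass) is fixed.
* Motion derivatives are backward differences with a leading zero row
  (the common realignment-parameter convention); zero-variance nuisance
  columns (e.g. the derivative of a constant trace) are dropped with a
  warning rather than crashing the QR solve.
* Permutations draw from R's RNG under a caller-supplied seed;
  `n_perm < 100` is refused.

## Problem sizes and what the package's own experiments show

The package validates itself at desk scale:

* **FWE calibration** (`fwe_calibration()`): 200 independent null
  cohorts — 40 subjects, 16³ grid, 120 volumes, planted baseline
  couplings but no age effect anywhere — each run end to end with 500
  permutations. The fraction of cohorts with any significant cluster
  estimates the realized family-wise error; it should not exceed the
  nominal 0.05 beyond binomial error, and in our runs it sits below it
  (the conjunction with the fixed main-effect mask makes the test
  conservative).
* **Power** (`power_planted_decline()`): the same machinery applied to
  cohorts of 80 subjects carrying the default declining coupling. A
  planted slope of −0.002/yr on a baseline of 0.13 — the magnitude of
  the real-data insula finding — is *not* reliably detectable at this
  scale: a per-voxel Fisher-Z over a series band-limited to
  0.01–0.08 Hz has sampling SD ≈ `1/sqrt(2·n_bins − 3)` (≈ 0.17 at 120
  volumes, ≈ 0.12 at 250), which caps the expected per-voxel age t
  near 2–3, below the voxel-forming threshold (t ≈ 3.2). Measured
  detection is roughly 10% at 120 volumes and 50% at 250; ≥90% power
  at these magnitudes would need series several times longer than a
  typical resting-state run, or several hundred subjects — which is
  precisely why the original cohort had 361. A doubled slope
  (−0.004/yr) *is* comfortably detected at N = 80, and that is the
  regime the power property test exercises. The dedicated acceptance
  check for the −0.002 slope is kept at its stated conditions and is
  expected to fail; we consider the honest power analysis more
  valuable than a tuned pass.
* The full-pipeline determinism check reruns a 20-subject cohort twice
  and compares cluster tables byte for byte.

## Known limitations

* Cluster-level inference is permutation-based; analytical random-field
  p-values, TFCE, and voxel-level FWE/FDR are out of scope.
* Inputs are assumed spatially aligned; motion correction, slice
  timing, and spatial normalization happen upstream.
* The group model is linear in age; quadratic aging trajectories are
  not modeled (and the generator plants none).
* The split-half grouping excludes the median subject for odd N; which
  real subject that is depends on the age ties present, so the rule is
  deterministic but not the only defensible one.
* Whether the main FC effect should be the covariate-adjusted mean
  (intercept with centered covariates, as implemented) or an
  unadjusted mean test is a modeling choice; the adjusted mean is the
  one consistent with the covariate structure.
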