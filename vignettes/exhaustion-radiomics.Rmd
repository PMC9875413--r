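---
title: "Modelling CD8+ T cell exhaustion from PET radiomics: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling CD8+ T cell exhaustion from PET radiomics: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exhaustscope)
```

## The model in one paragraph

Terminally exhausted (PD-1^hi) CD8+ T cells accumulate in tumors after
ablative irradiation, peaking around days 7–14 and collapsing below baseline
by day 21; checkpoint blockade reinvigorates them in responsive models (B16)
but not in resistant ones (LLC). The imaging hypothesis is that a heavily
exhausted infiltrate coincides with a patchier FDG-uptake landscape —
suppressed foci against a less suppressed background — so neighbour-scale
homogeneity statistics of the lesion (GLCM inverse variance, homogeneity2)
fall, and contrast rises, as the terminal-Tex fraction grows. The package
turns that hypothesis into a tested pipeline: simulate tumors whose texture
is driven by a latent exhaustion state, extract the radiomic catalogs,
filter by test–retest concordance, select exhaustion-correlated features by
LASSO, refit the three-feature binary logistic T-exhaustion score, and
evaluate discrimination and calibration.

## The synthetic phantom generator

No animal imaging or flow-cytometry data are distributed, so the generator
is a first-class module, not a fixture. It emulates:

* **Geometry.** An ellipsoidal lesion with semi-axes 3.8 × 3.6 × 3.4 mm
  (≈ 195 mm³, a tumor at treatment start) in a 48³ grid of 0.5 mm isotropic
  voxels, with ±8% per-subject semi-axis jitter in cohorts. The mask is the
  exact rasterized ellipsoid.
* **Uptake.** Lesion activity corresponding to SUV 2 given the acquisition
  metadata (5.55 MBq injected dose, 20 g body weight); background at 10% of
  lesion base.
* **Exhaustion-coupled heterogeneity.** A pool of 80 cold-spot kernels
  (Gaussian suppression blobs, radii 0.25–0.5 mm, full depth 65% of local
  uptake) is drawn once per seed; a phantom activates the first
  `round(gain × 80 × terminal_tex_frac)` of them. Activating blobs by count
  from a fixed pool makes the suppressed structure *nested* across
  exhaustion levels at fixed seed — the property behind the monotone
  homogeneity checks — and keeps the ROI intensity range roughly stable, so
  the fixed-bin discretization window does not drift with exhaustion.
  Scaling blob *depth* instead would move the window and couple every
  histogram feature to exhaustion through the normalization rather than
  through spatial structure, which is why depth is fixed.
* **A texture-unrelated confounder.** Real lesions vary in overall uptake
  spread for reasons unrelated to T cell state (perfusion, necrosis
  gradients). Each subject carries a smooth macroscopic modulation field (a
  sum of four cosine modes, wavelength 3.5–6 mm, amplitude drawn from
  U(0.05, 0.3), gated by `heterogeneity_gain`). Without it, global
  dispersion statistics (variance, MAD) would be *by construction* the best
  exhaustion correlates and the selection stage would never need texture;
  with it, neighbour-scale features carry the cleaner signal, which is the
  regime the method is about.
* **Noise.** Additive Gaussian noise on activity (sd 5% of lesion base),
  smoothed with a 1.5 mm FWHM kernel mimicking reconstruction resolution,
  variance-preserving, floored at 1% of base. Full Poisson/OSEM
  reconstruction noise is out of scope.
* **Exhaustion timecourses.** `llc_rt_timecourse()` anchors the calibrated
  quantities: baseline terminal-Tex mean 0.40, flat to day 3, peak means
  0.72/0.73 at days 7/14 (inside the observed 69.44–76.35% window), 0.30 at
  day 21 (below baseline). `llc_ici_timecourse()` stays near 0.40–0.43
  (ICI-resistant); `b16_ici_timecourse()` falls 0.20 → 0.12
  (reinvigoration). Intermediate-day means and all sds (0.04–0.06) are
  package defaults interpolating those anchors, not reported measurements.
  Per-subject draws use a normal truncated to [0, 1] via inverse-CDF
  sampling, so a zero sd returns the mean exactly.
* **Test–retest pairs.** The retest scan re-realizes the same latent lesion
  with a ~1 mm repositioning shift (mask re-rasterized), a fresh noise
  realization, and a per-session lognormal global intensity rescale
  (log-sd 0.15, emulating uptake-time and glycemia variability). The rescale
  is what separates the feature families under the CCC filter: fixed-bin
  texture and histogram features are affine-invariant and survive, raw
  intensity statistics do not — the structure the robustness step is meant
  to produce.

What the generator does **not** emulate: scanner-specific reconstruction,
partial-volume effects at organ boundaries, respiratory motion, necrotic
cores, or any spatial correspondence between individual T cells and voxels.
Passing tests therefore demonstrate that the *pipeline* recovers a planted
image-level signal under realistic nuisance variation; they are not evidence
about any particular biological dataset.

## Feature definitions and numerical choices

* **Discretization**: fixed bin count, 64 levels over the ROI min–max;
  the maximum maps to level 64; a constant ROI maps to level 1. Fixed-bin
  count (rather than fixed bin width) makes texture features invariant to
  affine intensity rescaling, which the test suite asserts.
* **GLCM**: distance 1, the 13 unique 3D directions (canonical
  representative has first nonzero component positive), symmetric counting,
  matrices summed over directions before normalization. Entropies in bits
  with 0·log 0 = 0. `InverseVariance` on a purely diagonal matrix is 0 (the
  limit of vanishing off-diagonal mass); `Correlation` is 0 when a marginal
  is degenerate.
* **GLRLM**: maximal runs per direction, summed over the 13 directions;
  run percentage divides by voxels × directions. A fully homogeneous region
  yields a single run and is valid.
* **First-order**: population (1/n) moments; kurtosis is Pearson
  (non-excess) `m4/m2²` in both the raw-intensity and histogram flavors — a
  normal sample gives ≈ 3. A constant ROI sets skewness and kurtosis to 0
  and flags the vector (`degenerate` attribute). The raw-intensity list
  follows the standard pyradiomics-style set (including robust MAD over the
  10–90 percentile range).
* **Shape** (CT catalog): volume is voxel count × voxel volume. Surface
  area comes from a marching-tetrahedra iso-surface at level 0.5 of the
  mildly smoothed mask (σ = 0.7 voxels) with interpolated edge crossings:
  smoothing leaves flat axis-aligned faces exactly on the voxel boundary but
  lets curved surfaces converge to their true area instead of the ~50%
  staircase overestimate a raw binary mesh produces. Consequences, both
  tested: a digital ball of radius 10 has Compactness2 within a few percent
  of 1, and a cube's Compactness2 converges to the closed form π/6 from
  above as the cube grows (≈ 0.57 at side 40). The convex hull volume uses
  an in-package incremental 3D hull over surface-voxel centers, exact on
  lattice polytopes; the maximum 3D diameter is taken over hull vertices.
* **Catalogs**: the shipped manifests fix the 61 PET / 57 CT compositions.
  PET = 19 raw-intensity + 10 histogram + 21 GLCM + 11 GLRLM; CT adds the
  9 shape features and omits 13 PET-only entries. Both contain every feature
  the score and selection tables reference.
* **CCC**: population-moment (1/n) form; the 1/(n−1) form differs
  negligibly at these n. Identical constant series give CCC 1 by convention;
  other degenerate cases give 0 with a flag. Retention is strict
  (`CCC > threshold`), thresholds 0.65 (PET) / 0.75 (CT) as configuration
  defaults. Why the thresholds differ per modality is treated as given
  configuration.
* **LASSO**: `glmnet` with internal standardization, leave-one-out folds in
  fixed order, smallest-deviance penalty (the one-standard-error rule is
  off, trading null sparsity for determinism — under permuted labels the
  selection is exactly empty in only ~60% of replicates, with a small-count
  tail). Continuous characteristics use the linear link; the binarized label
  uses the logistic link. Whether the original per-characteristic table came
  from linear or logistic penalized fits is not recoverable; both are
  supported and neither is claimed to match numerically.
* **The score refit**: unpenalized `glm` logistic fit of the median-split
  outcome on three features, bounded at 100 IRLS iterations. The synthetic
  planted signal is strong enough that cohorts are often completely
  separable; the bounded fit then returns a finite separating direction with
  confident probabilities, which is accepted rather than treated as an
  error. Two consequences are handled explicitly: the C-index is computed on
  the linear score (rank-equivalent to the probability, but immune to the
  exact-0/1 ties that `plogis` produces in floating point at large |score|),
  and per-feature directionality checks use univariate fits, because the
  joint coefficients of nearly collinear separable features have arbitrary
  signs.
* **The packaged reference score** carries exactly the constants
  −297.597, 178.689, 1.088 and intercept 1.485 with provenance
  `"packaged"`. Its absolute calibration belongs to the original acquisition
  and preprocessing, which are not recoverable; on synthetic phantoms it is
  rank-informative only.
* **Calibration curves** use 5 equal-width probability bins by default
  (binning unstated in the source material); empty bins are omitted and
  counts are conserved.
* **Median split**: ties at the median go to the low class, chosen for
  determinism.

## Study conditions and problem sizes

The default experiment (`run_config()`) uses cohorts of 20 subjects per arm:
training mixes LLC-like and B16-like ICI timecourses over days 0/7/22 (10
subjects each), validation follows the LLC post-irradiation timecourse over
days 0–21, and the robustness filter uses a separate 20-subject paired
test–retest cohort. Twenty per arm is a deliberate departure from the
3-mice-per-group scale of the motivating experiments: median-split logistic
modelling and LOO-penalty selection are unstable below ~10 subjects, and 20
keeps the full pipeline run under a minute on one CPU. Unit tests use
cohorts of 8–12 and the same phantom defaults. All randomness flows from a
single master seed through fixed per-subject seed derivation, so every run,
table and metric is bit-reproducible.

## Known limitations

* The phantom's exhaustion-texture coupling is designed, not fitted to
  images; effect sizes are chosen so the planted signal is strong (training
  C-index typically 1.0, validation 0.92–1.0 across seeds), so the reported
  metrics exercise the printed values as *bounds*, not as estimates of
  animal-study performance.
* Feature values are not expected to match any external implementation's
  numbers on real scans: the original extraction settings (resampling, bin
  configuration) are unpublished. The reproduction surfaces are the printed
  model constants, the catalog sizes, and the qualitative
  homogeneity–exhaustion directionality.
* The CT volume is a smooth density carrier for the shape/texture machinery,
  not a calibrated HU model.
* `Compactness2` of small rasterized shapes carries a resolution-dependent
  bias of order 1/side (see the shape notes above); comparisons across masks
  of similar size are safe, absolute values near the ideal limits are not.
* The convex hull assumes non-degenerate 3D masks; coplanar masks return
  hull volume 0 rather than an error.
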