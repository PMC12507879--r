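---
title: "Cohort-level muscle-fat habitat imaging: models, defaults and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cohort-level muscle-fat habitat imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(sarcohab)
```

## The model

`sarcohab` treats the voxel intensities inside a paraspinal-muscle ROI as
draws from a two-component mixture — one muscle component, one fat
component — whose polarity depends on the modality: on CT fat is hypodense
(around −90 HU against ~+50 HU muscle), on non-fat-suppressed T2-weighted
MRI fat is hyperintense. The segmentation question is therefore a 1-D
two-class clustering problem, and the package answers it at the *cohort*
level: ROI intensities of all training subjects are concatenated into one
global vector, one model is fitted, and a single scalar threshold is applied
to every subject. Cohort-level fitting trades per-case adaptivity for
stability and strict comparability across subjects, and cleanly separates
training from validation: thresholds are estimated on training subjects only
and frozen before they touch a validation ROI.

Three threshold derivations are implemented from scratch, because the
derivation itself is the method under study:

* **Otsu** — exhaustive search over the interior boundaries of a 256-bin
  equal-width histogram for the boundary maximising the between-class
  variance $\omega_0\omega_1(\mu_0-\mu_1)^2$. Ties are broken toward the
  smallest boundary, which makes the result deterministic even when the
  inter-peak valley contains empty bins (where the criterion is exactly
  flat).
* **k-means** — 1-D two-cluster k-means with k-means++ initialisation,
  Lloyd iterations (max 300), 10 restarts keeping the best within-cluster
  sum of squares, and empty clusters re-seeded at the farthest point. The
  initial boundary is the centroid midpoint, i.e. the point where the
  nearest-centroid assignment flips.
* **GMM** — a two-component Gaussian mixture fitted by EM, initialised from
  the k-means solution (means = centroids; weights and variances from the
  k-means partition). The E-step runs in log space; convergence is declared
  when the relative log-likelihood change drops below `tol = 1e-6` (max 500
  iterations); variances are clamped at `1e-6 * var(values)` to prevent
  component collapse. The initial boundary is the equal-posterior point
  $w_1\,\mathcal N(t;\mu_1,\sigma_1^2) = w_2\,\mathcal N(t;\mu_2,\sigma_2^2)$
  between the two means, solved in closed form (quadratic), with a midpoint
  fallback for degenerate fits.

### Threshold refinement

All three initial boundaries pass through the same refinement: the pooled
histogram is smoothed with a centred moving average (window 5 bins, raw
counts are too noisy for reliable peak positions), the highest local maxima
below and above the initial boundary are taken as the muscle and fat peaks,
and Otsu is re-run on the values restricted to the closed inter-peak
interval; the refined value is the final threshold. If two flanking peaks
cannot be found (e.g. heavily smeared MRI histograms) the initial boundary
is kept and a warning is emitted. The exact refinement procedure was a
genuinely open design point; this peak-restricted-Otsu interpretation was
chosen because it uses the peak positions for exactly one purpose —
insulating the Otsu criterion from the far tails — and reduces to plain
Otsu on clean bimodal data (a property the test suite asserts). A
consequence worth knowing: after refinement the three methods often agree
to within a bin width on well-separated data, since they are then all
essentially locating the same valley.

### Classification and features

Voxels at or below the threshold are fat on CT; at or above it, fat on MRI
(the boundary-equal case goes to fat on both — a deterministic tie rule
with measure-zero effect on continuous data). Per subject the six habitat
features are the fat/muscle mean intensity, volume (voxel count × voxel
volume; 1 mm³ after resampling to the isotropic grid) and volume fraction.
Fractions are kept in [0, 1] internally and only rendered as percentages in
reports, to avoid double-scaling bugs. An empty habitat yields a missing
mean (never 0, which is a valid intensity), zero volume and zero fraction.

### Evaluation protocol

Subjects are split 6:4 into training and validation, stratified by label
(stratification stabilises small-class folds; within each class
`round(0.6 n)` go to training). Candidate predictors pass a univariate
logistic screen at p < 0.05; the multivariate model is then reduced by
backward stepwise elimination, removing the largest-Wald-p predictor while
that p exceeds 0.05, and stopping at one predictor. Two deliberate choices
here:

* The *screening* p-value is a likelihood-ratio test, not Wald. Strongly
  predictive imaging features routinely produce quasi-complete separation,
  under which the Wald statistic collapses toward zero (Hauck–Donner) and
  would reject exactly the strongest candidates; the LRT does not suffer
  from this. Stepwise *removal* stays Wald-based, matching the reported
  odds-ratio/CI tables, and separation is flagged on the fitted object
  rather than raised as an error.
* Exactly collinear candidates (fat and muscle volume fractions always sum
  to one) are dropped by QR pivot before the multivariate fit, keeping
  first occurrences; a user-supplied duplicated column is still a hard
  rank-deficiency error.

AUC is the Mann–Whitney statistic with ties counted ½; its 95% CI uses
DeLong's placement-based variance. Operating points maximise the Youden
index over midpoints of consecutive distinct scores (±∞ included), with
ties broken by higher sensitivity and then lower cutoff; sensitivity,
specificity and accuracy come from the confusion counts at that cutoff.
Model stability is assessed by stratified five-fold cross-validation in
which the *entire* recipe (screen → alias drop → stepwise) is refit per
fold. Observer agreement uses ICC(2,1) — two-way random effects, single
measure, absolute agreement — computed from ANOVA mean squares.

## The synthetic cohort generator

No public imaging accompanies this problem, so the generator is a
first-class module that emulates the statistical structure the analysis
assumes, with known voxel-level truth:

* **ROI geometry.** An ellipsoid centred in a 40×40×16 voxel grid, radii
  0.42 of each dimension jittered ±10% per axis (≈ 8,000 voxels ≈ 8 cm³ at
  1 mm isotropic). Sarcopenia shrinks the radii by factor 0.97 (~9% volume):
  compartment-level atrophy is kept modest because muscle loss is partly
  replaced by fat within the delineated compartment, making fat fraction,
  not ROI volume, the dominant marker — consistent with the weak volume
  odds ratios reported in this literature. The grid size was chosen so that
  a default training pool (~0.9 M voxels) resolves the inter-peak valley of
  the pooled histogram; with pools an order of magnitude smaller, the
  valley contains long runs of empty bins and the smallest-boundary tie
  rule biases Otsu left of the population optimum.
* **Tissue truth and intensities.** Each subject draws a true fat fraction
  from N(group mean, 0.07²) truncated to [0, 1] — defaults 0.15
  (non-sarcopenia) vs 0.45 (sarcopenia), a strong, well-separated effect —
  then labels ROI voxels i.i.d. Bernoulli and draws intensities from the
  corresponding Gaussian component. CT: muscle +50 HU, fat −90 HU, SD 15;
  MRI: muscle 300, fat 900, SD 120 on an arbitrary T2w scale.
* **Scanner variation.** A per-subject additive offset N(0, jitter²) with
  jitter 3 HU on CT and 60 on MRI, plus, on MRI only, a multiplicative
  log-normal gain (sdlog 0.4). Multiplicative gain is the physically
  appropriate model for uncalibrated receiver chains, where cross-scanner
  signal ratios of 2–3× occur; it preserves positivity. These defaults make
  MRI intensities much less standardised than CT — deliberately, so the
  fixed cohort-level threshold misclassifies variable fractions of MRI
  voxels per subject and MRI models underperform CT models, the qualitative
  ordering this pipeline is designed to exhibit. An optional per-subject
  median rescaling (`median_scale_cohort()`) is provided for users who want
  to standardise MRI before pooling, but it is off by default everywhere:
  whether such normalisation belongs in the protocol is ambiguous, and the
  default reproduces the harder, unnormalised condition.
* **Covariates.** Age, BMI, albumin, hemoglobin and red-cell count are
  drawn from group-specific normals (e.g. age 68.1 ± 6.9 vs 71.7 ± 7.0
  years; BMI 24.99 ± 3.40 vs 22.83 ± 3.18 kg/m²; albumin 37.9 ± 3.1 vs
  35.9 ± 3.3 g/L) matching published sarcopenia-cohort summaries.
  Covariates are drawn independently; only marginal distributions are
  emulated, not their correlation structure.
* **Seeds.** Every subject's seed derives from the master seed through a
  splittable counter scheme, and anatomy (fat fraction, geometry, labels,
  covariates) is drawn from a stream salted separately from intensities —
  so the same master seed images the *same* synthetic patients on CT and
  MRI. All stochastic entry points take explicit seeds and restore the
  caller's RNG state.

What the generator does **not** emulate: spatial structure (voxels are
i.i.d., so there is no partial-volume mixing, no texture, no anatomy-shaped
ROI), bias fields, DICOM provenance, or covariate correlations. Volumes are
produced directly on the 1 mm isotropic analysis grid: interpolating across
spatially independent mixture draws would average neighbouring components
and destroy the bimodality the segmentation relies on, so resampling is
exercised on analytic fixtures (constants, linear ramps, checkerboards)
rather than on generated cohorts. Passing tests therefore demonstrate that
the *algorithms* recover known mixtures and orderings — not that the
pipeline handles anatomically realistic images.

## Default problem sizes

The default experiment uses 100 + 100 subjects per modality
(120 training / 80 validation after the 6:4 split), pooling roughly
0.9 million training voxels, and completes in about a minute on one CPU.
At these sizes the cohort-level thresholds land within ~2 histogram bin
widths of the analytic equal-posterior boundary of the generating mixture,
per-subject fat-percent estimates sit within binomial noise of the true
fat fractions, and validation AUCs separate CT (≥ 0.95) from MRI (~0.8).
Test fixtures use much smaller grids (e.g. 14×14×8) where speed matters
more than histogram resolution.

## Degenerate inputs and numerical edges

* Constant intensity vectors are a `degenerate` error for all three
  fitters; a one-bin histogram likewise.
* EM on effectively unimodal data either drives both means together or one
  weight to its floor; both outcomes are accepted, NaNs are not.
* Variance floors (`1e-6 × var`) and log-space responsibilities keep EM
  finite on heavy-tailed pools.
* `fat_fraction = 0` (or 1) is a valid degenerate configuration: a
  pure-muscle (pure-fat) ROI with the fraction recorded exactly.
* Empty habitats propagate missing means; models drop incomplete rows
  listwise.
* An empty resampled mask warns at resampling time and errors downstream
  at extraction, where the ROI contract is enforced.

## Known limitations

Cohort-level thresholds assume a shared intensity scale across subjects;
on uncalibrated MRI this assumption is exactly what degrades performance,
and that behaviour is intended. The refinement step makes the three
methods nearly indistinguishable on well-separated data, so method
rankings observed on real cohorts (where separation is partial) will not
reproduce at full strength on the synthetic defaults. ICC utilities expect
complete rating matrices; there is no missing-rating support. The package
does not compare AUCs between models formally (no paired DeLong test) and
does not model calibration.
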