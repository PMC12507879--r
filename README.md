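# sarcohab

Unsupervised muscle–fat habitat imaging of the paraspinal muscles for
sarcopenia prediction.

## The problem

Sarcopenia — age-related loss of skeletal muscle mass and quality — is
routinely assessed on cross-sectional imaging at the L3/4 level, where fat
infiltration of the paraspinal muscles is a key marker. On CT, fat is
hypodense relative to muscle (negative Hounsfield units vs. ~+50 HU); on
non-fat-suppressed T2-weighted MRI the polarity flips and fat is
hyperintense. `sarcohab` implements a *cohort-level* unsupervised
segmentation of ROI voxels into muscle and fat habitats: instead of
clustering each patient separately, voxel intensities from all training
subjects are pooled into one global vector, a two-class cluster model is
fitted once, and the derived scalar threshold is applied to every subject —
training and validation alike.

Three threshold derivations are provided:

- **Otsu**: exhaustive maximisation of the between-class variance
  ω₀ω₁(μ₀−μ₁)² over the 256-bin intensity histogram;
- **k-means**: 1-D two-cluster k-means (k-means++ initialisation, Lloyd
  iterations, 10 restarts); threshold = centroid midpoint;
- **GMM**: two-component Gaussian mixture fitted by EM (initialised from
  k-means); threshold = the equal-posterior boundary
  w₁ N(t; μ₁, σ₁²) = w₂ N(t; μ₂, σ₂²) between the means.

Each initial boundary is then refined by re-running Otsu on the histogram
restricted to the interval between the two smoothed-histogram peaks flanking
it. Per-subject habitat features (fat/muscle mean intensity, volume, volume
percentage) feed the evaluation protocol: stratified 6:4 split, univariate
screening, backward-stepwise multivariate logistic regression, ROC/AUC with
DeLong 95% CIs and Youden-optimal cutoffs (J = sensitivity + specificity − 1),
five-fold cross-validation, and ICC(2,1) for observer agreement.

Because no real imaging is bundled, the package ships a synthetic cohort
generator with voxel-level ground truth (two-component intensity mixtures
with modality-correct polarity, group-shifted fat fractions, scanner jitter,
and clinical covariates), so the whole pipeline is testable against known
truth.

## Worked example

```r
library(sarcohab)

cfg <- run_config(
  modalities = "CT", methods = c("otsu", "gmm"),
  n_non_sarcopenia = 30, n_sarcopenia = 30,
  roi_shape = c(24, 24, 10), seed = 42
)
exp <- run_experiment(cfg)
exp
#> <habitat_experiment> 60 subjects, CT; otsu/gmm
#> # A tibble: 3 × 6
#>   modality method   status train_auc validation_auc cv_mean_auc
#>   <chr>    <chr>    <chr>      <dbl>          <dbl>       <dbl>
#> 1 CT       otsu     ok         1              0.958       1
#> 2 CT       gmm      ok         1              0.958       1
#> 3 clinical clinical ok         0.744          0.681       0.701
```

The cohort-level GMM recovers the generating mixture — the synthetic CT fat
component is N(−90, 15²) plus per-subject offsets, muscle N(+50, 15²), and
the pooled training fat weight is ~0.3:

```r
cm <- exp$cluster_models$CT_gmm
cm
#> <cluster_model> gmm (CT), threshold -22.37 (refined from -21.45), fitted on 62976 voxels
tidy(cm)
#> # A tibble: 2 × 4
#>   component weight  mean variance
#>   <chr>      <dbl> <dbl>    <dbl>
#> 1 low        0.307 -90.4     241.
#> 2 high       0.693  49.7     237.
```

The derived threshold (−22.4 HU) separates fat from muscle voxels; habitat
features built from it give a validation ROC of:

```r
glance(exp$results$detail[[2]]$roc_validation)
#> # A tibble: 1 × 8
#>     auc auc_low auc_high cutoff sensitivity specificity accuracy youden
#> 1 0.958   0.877        1  0.500       0.917           1    0.958  0.917
```

i.e. the imaging model identifies 11/12 validation sarcopenia subjects with
no false positives at the Youden-optimal probability cutoff. `autoplot()`
methods display the pooled histogram with its threshold, ROC curves, and
axial habitat maps (muscle blue, fat red).

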