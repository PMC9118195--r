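# vaporclass

Tissue classification and sensitivity analysis for ambient ionization
mass spectrometry.

Rapid evaporative ionization mass spectrometry (REIMS, the "iKnife"
principle) turns the vapor of electrosurgical cautery into one metabolic
profile per burn, enabling near-real-time recognition of tumor versus
normal tissue during surgery. For infiltrative cancers the decisive
question is sensitivity: the smallest fraction of tumor cells in the
cauterized volume that the classifier still detects. vaporclass is an R
package for the computational side of that workflow, aimed at analysts
working with REIMS or DESI-MSI metabolic profiles:

* **Preprocessing** — burn-scan selection from the ion chromatogram,
  single-point multiplicative lock-mass recalibration against
  leucine-enkephalin, 0.1 Th binning with exact intensity conservation,
  exclusion-window masking, background subtraction, TIC normalization,
  and k·SD outlier screening (`preprocess_cohort()`, `flag_outliers()`).
* **Classification** — PCA for data reduction, Fisher LDA on the
  component scores with nearest-centroid calls, and leave-one-group-out
  cross-validation (one fold per patient or biological replicate) with
  pooled confusion matrices (`fit_pca_lda()`, `cross_validate_logo()`).
* **Sensitivity / limit of detection** — the iterative truth-threshold
  ROC for dilution series: predictions stay fixed while the tumor/muscle
  ground-truth boundary θ sweeps across the known tumor fractions
  (truth = tumor iff f > θ); each θ yields a full confusion matrix and an
  (FPR, TPR) point, the AUC is the trapezoid over the anchored curve, its
  SE is Hanley–McNeil, the best cutoff maximises Youden's J, and
  `detection_limit()` returns the smallest fraction meeting required
  sensitivity/specificity bounds (`iterative_roc()`).
* **Spectral unmixing** — exact simplex-constrained least squares
  (min ‖s − Pw‖₂ s.t. w ≥ 0, Σw = 1) of mixture spectra against pure
  class profiles (`unmix()`).
* **MSI** — imzML IO, six-adjacent-pixel region profiles, seeded k-means
  segmentation, extracted ion images, peak picking with baseline
  correction and deisotoping (`roi_group_profiles()`, `kmeans_segment()`,
  `ion_image()`, `peak_pick()`).
* **Synthetic data** — a fully seeded generator (class peak templates,
  per-group effects, burn-shaped TIC series, mass drift, baseline,
  aberrant spectra, dilution and MSI designs) so every stage runs and is
  tested without instrument data (`make_templates()`,
  `simulate_cohort()`, `simulate_dilution_series()`,
  `simulate_msi_grid()`).

Everything is tibble-first: feature matrices are wide tibbles (metadata
columns plus `mz_*` bin columns), fitted objects have broom-style
`tidy()`/`glance()` methods, and result types have `autoplot()` methods.

## Worked example: detection limit of a dilution series

A scaled-down tumor/myoblast dilution experiment (tumor fractions
100/50/25/10/0 %, 72 burns) under the package's separable study
conditions, classified with a two-class PCA-LDA model under
leave-one-replicate-out cross-validation:

```r
library(vaporclass)
library(dplyr)

setup <- separable_dilution_setup(7)
dil <- simulate_dilution_series(
  setup$config, setup$templates,
  n_per_point = c(20, 10, 12, 10, 20)   # scaled-down dilution design
)
fm <- preprocess_cohort(dil$series, reims_cells_config())
fm$class_label <- dil$truth$class_label
fm$group_id    <- dil$truth$group_id

(cv <- cross_validate_logo(fm, n_pc = 10))
#> <cv_result: accuracy 0.986 over 72 samples, 5 folds>
#>         predicted
#> actual   muscle tumor
#>   muscle     20     0
#>   tumor       1    51

preds <- left_join(tidy(cv), dil$truth, by = "sample_id")
(roc <- iterative_roc(preds))
#> <roc_curve: AUC 0.997 +/- 0.005 over 72 samples, 4 thresholds>
#> # A tibble: 4 × 7
#>   theta    tp    fn    fp    tn   tpr   fpr
#>   <dbl> <int> <int> <int> <int> <dbl> <dbl>
#> 1  0       51     1     0    20 0.981 0
#> 2  0.1     42     0     9    21 1     0.3
#> 3  0.25    30     0    21    21 1     0.5
#> 4  0.5     20     0    31    21 1     0.596

detection_limit(roc, min_tpr = 0.8, min_specificity = 0.8)
#> [1] 0.1
```

Reading the output: the cross-validated two-class model misses one
tumor-containing burn (98.6% accuracy). At truth threshold θ = 0 every
mixture containing any tumor counts as truly tumor and the model detects
98.1% of them at 100% specificity; as θ rises, low-fraction mixtures
predicted "muscle" stop counting as errors, tracing the iterative ROC.
The smallest design fraction whose immediately-lower threshold achieves
at least 80% sensitivity and 80% specificity is 0.1, i.e. a 10% tumor
admixture is still detected. `autoplot(roc)` draws the curve;
`autoplot(cv)` draws the confusion matrix.

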