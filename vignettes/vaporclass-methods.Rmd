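---
title: "Methods: spectral preprocessing, PCA-LDA classification and the iterative-ROC detection limit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spectral preprocessing, PCA-LDA classification and the iterative-ROC detection limit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vaporclass)
library(dplyr)
```

## The problem

Rapid evaporative ionization mass spectrometry (REIMS) analyses the vapor
produced by electrosurgical cautery and returns one negative-mode metabolic
profile per "burn".  Matched against a library of histology-annotated
profiles, this allows near-real-time recognition of tumor versus normal
tissue during surgery.  For infiltrative tumors such as oral squamous cell
carcinoma the clinically decisive question is *sensitivity*: what is the
smallest fraction of tumor cells in the cauterized volume that the
classifier still detects?  vaporclass implements the computational side of
that question end to end: spectral preprocessing, PCA-LDA classification
with leave-one-group-out cross-validation, a dilution-series ROC procedure
that estimates the limit of detection, linear unmixing of mixture spectra,
and the companion DESI-MSI imaging computations — all exercisable on
synthetic spectra so that every stage is testable without instrument data.

## Preprocessing chain

The canonical chain is

> burn-scan selection → lock-mass recalibration → 0.1 Th binning →
> exclusion-window masking → background subtraction → TIC normalization,

with outlier screening applied afterwards on the assembled feature matrix.
The tunables, their defaults and the reasoning:

* **Burn-scan selection** (`select_burn_scans()`).  Tissue workflows take
  the single scan with maximal total ion current per sampling spot
  (`one_per_spot`); cell-pellet workflows take the scans at the top of the
  burn signal (`top_of_peak`).  "Top" is defined as the contiguous block
  around the TIC maximum staying at or above 70% of it; the fraction is a
  package choice (exposed as `top_frac`) since no published value exists.
  When one profile per event is required, the selected scans are pooled
  (their peak lists concatenated) before binning.
* **Lock-mass correction** (`lockmass_correct()`).  A single-point
  multiplicative (ppm) correction against continuously infused
  leucine-enkephalin: the most intense peak within ±0.25 Th of the
  reference is pulled onto it, scaling all m/z by the same factor.  The
  multiplicative law is the natural model for time-of-flight mass error.
  The reference defaults to the monoisotopic [LeuEnk−H]⁻ mass,
  554.2615 Th (display conventions round this to 554.3); it is a config
  field, never hard-coded.  If no peak lies in the window the spectrum is
  left untouched and flagged, because silently guessing a correction is
  worse than none.
* **Binning** (`bin_spectrum()`).  Half-open bins `[edge, edge + 0.1)`
  anchored at the lower end of the mass range (100–1500 Th for tissue,
  600–1000 Th for cells, 600–900 Th for the five-class cell model).  Every
  in-range peak lands in exactly one bin, so in-range intensity is
  conserved exactly — this is asserted bit-for-bit in the tests.
* **Exclusion windows** (`apply_exclusions()`).  The tissue workflow
  zeroes every bin intersecting m/z 554–558, 594–597, 1109–1112 and
  1131–1137, i.e. the lock-mass ion and its associated peaks, which carry
  no tissue information.  (The third window is stated inconsistently in
  some method descriptions; 1109–1112 is the only reading consistent with
  the window widths around it.)
* **Background subtraction** (`background_subtract()`).  The published
  chains name the step but not the estimator.  We subtract the 5th
  percentile of the non-zero bin intensities from every non-zero bin,
  clipping at zero: a simple, monotone estimator that removes a diffuse
  pedestal, cancels constant offsets exactly, and is trivially testable.
  The method is a single function and can be swapped.
* **Normalization** (`normalize_tic()`).  Division by the summed
  intensity.  Whether the reference software normalizes to TIC or to a
  median is unpublished; TIC is the common choice and is flagged here as
  an assumption.  The operation is idempotent.
* **Outlier screening** (`flag_outliers()`).  "Deviates by k standard
  deviations" is codified as: within each class, compute each sample's
  Euclidean distance to the class mean profile and flag samples whose
  distance exceeds the class mean distance by more than `k` SDs of those
  distances (k = 5 for tissue, 25 for cells).  Classes with fewer than
  three members are never flagged.  Flagged samples are reported, never
  silently dropped.  Note the rule's intrinsic masking limit: the
  aberrant samples themselves inflate the distance SD, so it is reliable
  only while aberrant spectra are rare (a few percent at most) and
  grossly displaced — exactly the regime it is meant for.

## PCA-LDA classification

`fit_pca()` is a centered singular value decomposition with a fixed sign
convention (the largest-magnitude element of each loading is positive) so
that score plots reproduce across platforms.  `fit_pca_lda()` feeds the
first `n_pc` component scores (default 10, matching the published
five-class cell model "10 PC, 4 LDA") to Fisher linear discriminant
analysis: discriminant directions maximise between-class over pooled
within-class scatter, with a 1e-6 ridge on the within-scatter diagonal
purely for conditioning.  `n_ld` defaults to `n_classes − 1`.
Classification is by nearest centroid in discriminant space; ties go to
the lexicographically first class and are logged; per-class scores are
softmin-transformed centroid distances summing to one.

`cross_validate_logo()` implements leave-one-group-out cross-validation —
one fold per patient (tissue) or biological replicate (cells) — refitting
the full PCA-LDA pipeline per fold, so no subject-level information leaks
into the held-out predictions.  A fold that would remove an entire class
from training is an error, not a silent skip.  `harmonize_bins()` restricts
two feature matrices to their common bin axis and renormalizes, enabling
cross-platform prediction (e.g. a model trained on one modality applied to
another's mass range).

## The iterative truth-threshold ROC

The dilution assay mixes tumor and myoblast cell suspensions at known
cell-count fractions (100/0, 50/50, 75/25, 90/10, 0/100) and asks when the
classifier stops seeing the tumor.  The two-class model is trained with
"tumor" assigned to every mixture with at least 10% tumor cells and
"muscle" to pure myoblast pellets only (`assign_binary_labels()`;
fractions strictly between 0 and the cutoff are indeterminate and excluded
from training).

`iterative_roc()` then sweeps the *ground truth* while predictions stay
fixed: at truth threshold θ a sample counts as truly tumor iff its known
fraction exceeds θ strictly, so at θ = 0.10 the 10% mixtures that were
predicted muscle count as correctly classified.  Each θ (the distinct
design fractions except the largest) yields a full 2×2 confusion and one
(FPR, TPR) point; the curve is anchored at (0,0) and (1,1) and the AUC is
the trapezoid area over the points sorted by FPR.  The strict inequality
at the boundary is deliberate and matches the published description of the
second iteration.  The AUC standard error uses the Hanley–McNeil formula
with the class sizes at the lowest threshold (the estimator behind
published ± values on AUCs is typically unstated; Hanley–McNeil is the
standard choice).  `best_cutoff()` maximises Youden's J = TPR − FPR with
ties going to the smaller (more sensitive) threshold.

`detection_limit(roc, min_tpr, min_specificity)` codifies "the smallest
tumor fraction detectable at acceptable sensitivity and specificity": the
smallest non-zero design fraction f whose immediately-lower truth
threshold achieves TPR ≥ `min_tpr` and specificity ≥ `min_specificity`
(both default 0.8).  Because predictions are hard class calls, a
score-based conventional ROC over the continuous tumor score is provided
separately (`score_roc()`, delegated to pROC) for when the classifier's
scores are of interest.

## Linear unmixing

`unmix()` estimates each mixture spectrum's composition as the convex
combination of pure class profiles best fitting it in least squares:
minimise ‖s − Pw‖₂ subject to w ≥ 0, Σw = 1.  With the small numbers of
pure profiles involved (two to five), the problem is solved *exactly* by
enumerating support sets: for each non-empty subset of components the
sum-constrained least-squares solution is obtained in closed form from the
KKT system, infeasible (negative) solutions are discarded, and the best
feasible one is kept.  Collinear pure profiles trigger an ill-posedness
warning but still return the best solution with its residual.  Estimated
weights are *signal* fractions: they equal cell-count fractions only when
the classes ionize equally well (see below).

## MSI computations

* `roi_group_profiles()` combines groups of six adjacent pixels inside
  each pathologist-annotated region into one profile (sum, then TIC
  normalization).  "Adjacent" is realized as row-major scanline order
  within the region — the acquisition order of a line-scanning DESI stage —
  since no published adjacency pattern exists; leftover pixels are dropped
  with a logged count, so the profile count per region is exactly
  ⌊pixels/6⌋.
* `kmeans_segment()` clusters TIC-normalized binned pixels with k-means
  (10 random restarts, Euclidean distance, seed from the call), returning
  a label image and cluster mean spectra.  Distances are computed on
  normalized, not log-transformed, intensities; restarts and seed make the
  segmentation reproducible.
* `ion_image()` sums per-pixel intensity in a ±0.05 Th window (half a bin)
  around the target, e.g. m/z 698.5 (ether-phosphatidylethanolamine
  PE(O-16:1/18:2)) or 465.3 (cholesterol sulfate).  Missing pixels stay
  missing rather than being reported as zero.
* `peak_pick()` mirrors a conventional average-spectrum chain: a 10 Th
  rolling-minimum baseline (applied only where the window holds at least
  8 data points, so an isolated centroid peak is never its own baseline),
  a signal-to-noise gate at 3 MADs, and greedy ascending-m/z deisotoping
  that removes peaks lying 1.00335 ± 0.01 Th above a more intense peak of
  the same envelope.  Envelope membership chains: the A+2 ion is removed
  via the (already removed) A+1 ion, not by comparison with the
  monoisotopic peak alone.
* Histology registration is out of scope; regions of interest enter as a
  plain `(x, y, label)` table produced elsewhere.

## The synthetic generator

`make_templates()` draws class-specific peak templates on the 0.1 Th grid:
a configurable fraction of peak positions is shared across classes (with
independent intensities), the rest are class-exclusive; relative
intensities are exponential draws normalized to one.  `simulate_spectrum()`
forms the ionization-efficiency-weighted convex combination of templates,
applies per-group (patient / biological replicate) log-normal effects,
multiplicative Gaussian peak noise, a diffuse random baseline, the
lock-mass ion and a uniform ppm mass drift.  `simulate_cohort()` acquires
each sample as an eight-scan burn with a triangular rise–plateau–fall TIC
so burn-scan selection is exercised; `simulate_dilution_series()`
reproduces the dilution design (93/44/57/49/93 burns at tumor fractions
1/0.5/0.25/0.1/0, pure points over five biological replicates, mixtures
over three); `simulate_msi_grid()` draws one spectrum per mapped pixel.
Everything is driven by a mandatory seed and is bit-reproducible.

Default levels, chosen once as a realistic benchtop acquisition and fixed:
peak CV 0.15, group-effect log-SD 0.1, baseline 2% of TIC over 50
positions, drift uniform in ±20 ppm, lock-mass at 5% of TIC, aberrant
spectra off unless requested.  Aberrant spectra model contamination burns:
random contaminant peaks swamping the signal at ten times its intensity.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: isotope envelopes (except in the dedicated
peak-picking fixtures), chemical noise correlated across samples,
detector saturation, real lipidomic peak structure, and drift that evolves
over a surgery-length acquisition.  Synthetic separability is an upper
bound on real-world performance, which is why the package's acceptance
checks are calibration and recovery properties rather than claims about
clinical accuracy.

## Why 10% mixtures need an ionization-efficiency asymmetry

One design question deserves its own section.  After TIC normalization a
noiseless mixture spectrum with equal ionization efficiencies is *linear*
in the tumor cell fraction f: every linear functional of the profile is
affine in f.  A nearest-centroid linear classifier therefore splits the
dilution axis at the midpoint between the muscle centroid (f = 0) and the
tumor-class centroid (the mean f of the tumor-labelled training mixtures,
≈ 0.55 for the 93/44/57/49 design) — about f ≈ 0.28.  No amount of noise
reduction changes this: under equal efficiencies the model *cannot* call
a 10% mixture tumor, and the detection limit saturates at the 25% design
point.

Real vapor profiles are not linear in cell count — ionization efficiency,
lipid content and burn behaviour differ between cell types, which is
precisely the qualitative-versus-quantitative tension discussed in the
ambient-ionization literature.  The generator exposes this through the
template's `ionization_efficiency` η: the signal share of a mixture is
fη_t / (fη_t + (1−f)η_m).  `separable_dilution_setup()` fixes the
"separable" study condition once — disjoint templates, low noise (CV
0.05, group effects 0.02) and η_tumor/η_myoblast = 10 — under which a 10%
cell mixture carries a 53% tumor signal share, the end-to-end experiment
reaches AUC 1, and the detection limit equals the smallest design
fraction, 10%.  Elsewhere the defaults keep η = 1, so unmixing recovery
is checked against cell-count fractions.

## Numerical choices and degenerate inputs

Bins are lower-edge labelled and anchored at the mass-range minimum;
feature-matrix columns are named `mz_<edge>` with edges rounded to 1e-6 Th
so axes match by name across matrices.  PCA/LDA sign conventions are
fixed as described.  Ties: equidistant centroids go to the first class in
lexicographic order; equal Youden's J goes to the smaller threshold; both
are logged.  Degenerate inputs error loudly: all-zero TIC series,
zero-sum normalization, empty truth classes at every ROC threshold,
cross-validation folds that lose a class, k-means with more clusters than
pixels.

## Problem sizes

The test-suite and acceptance-script cohorts use the designs above at
their natural sizes (185 tissue profiles over 5 patients, 220 cell
profiles over 3 replicates, 336 dilution profiles, 500-sample outlier
cohorts, 30×30 MSI grids, 200 random ROC designs against an exhaustive
enumeration oracle), which keeps the full suite in the low minutes on a
single core while exercising every stage at the published design shapes.

## Known limitations

* The detection-limit result is conditional on the separability argument
  above; with equal ionization efficiencies the linear pipeline is
  structurally blind below the ~25% design point.
* The outlier rule inherits the masking limitation of mean + k·SD
  statistics.
* imzML support covers the "processed", uncompressed, 64-bit layout that
  the package itself writes; mzML reading requires the Bioconductor mzR
  backend.
* Scores from `predict()` are softmin rankings, not calibrated
  probabilities.
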