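Package: vaporclass
Title: Tissue Classification and Sensitivity Analysis for Ambient Ionization
    Mass Spectrometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for rapid evaporative ionization mass
    spectrometry (REIMS) and desorption electrospray ionization imaging
    (DESI-MSI) metabolic profiles: spectral preprocessing (burn-scan
    selection, lock-mass recalibration, 0.1 Th binning, background
    subtraction, TIC normalization, outlier screening), PCA-LDA tissue
    classification with leave-one-group-out cross-validation, an iterative
    truth-threshold ROC procedure for estimating the limit of detection of
    tumor cells in dilution series, non-negative spectral unmixing of
    mixture spectra, and mass spectrometry imaging utilities (ROI pixel
    group profiles, k-means segmentation, extracted ion images, peak
    picking).  Includes a synthetic spectrum generator so that every stage
    is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    xml2
Suggests:
    mzR,
    mclust,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
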