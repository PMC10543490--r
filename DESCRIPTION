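Package: plexseg
Title: Atlas-Guided 3-D U-Net Segmentation and Lifespan Volumetry of the
    Choroid Plexus
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Patch-based 3-D convolutional segmentation of the choroid
    plexus from anatomical MRI contrasts (T1-weighted, T2-weighted and
    FLAIR), built around a probabilistic-atlas patch sampler, a compact
    3-D U-Net trained with a generalized Dice loss, and the evaluation
    machinery that goes with it: Dice, 95% Hausdorff distance, ROC AUC,
    intraclass correlation, Bland-Altman agreement, Wilcoxon tests with
    false-discovery-rate correction, and lifespan volumetry regressions
    with McFadden pseudo-R-squared. A synthetic head-phantom cohort
    generator emulates ventricles that enlarge with age and a bilateral
    plexus-like structure whose volume grows linearly with age, so the
    whole pipeline is testable without access to clinical imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
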