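Package: radtex
Title: Radiomic Texture Features and Wrapper-Based Classification for
    Multiparametric Prostate MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for radiomic analysis of paired T2-weighted
    and apparent-diffusion-coefficient (ADC) prostate MRI volumes with
    binary lesion masks. Computes twelve first-order histogram statistics,
    local binary patterns on three orthogonal planes (TOP-LBP, four
    variants), and three-dimensional grey-level co-occurrence matrix
    (GLCM3) texture descriptors over all 26 unit displacements; combines
    them with clinical covariates (digital rectal examination, maximum
    PI-RADS score); selects features by wrapper search with a random-forest
    evaluator and internal cross-validation; and evaluates clinically
    significant prostate cancer classification (Gleason score >= 7) by
    cross-validated ROC analysis with best-cutoff metrics and confidence
    intervals. Includes a seeded synthetic-cohort generator of two-class
    masked texture phantoms so the full pipeline is reproducible without
    patient data, and a command-line interface over the pipeline stages.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    RNifti,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    pROC,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
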