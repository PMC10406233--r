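Package: restqc
Title: Quality Control Metrics and Criteria for Resting-State fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative quality control for resting-state functional MRI:
    volume-to-volume motion (Euclidean norm of realignment-parameter
    differences), motion censoring, censored nuisance regression with exact
    degrees-of-freedom accounting (polynomial drift, tissue and motion
    regressors with temporal derivatives, band-pass via stop-band sine/cosine
    projection), image-quality metrics (temporal signal-to-noise ratio,
    spatial smoothness estimation and iterative blur-to-target, Dice mask
    overlap, left-right flip detection, functional connectivity strength),
    connectivity-level diagnostics (seed correlation maps, parcellated
    connectivity matrices with Fisher-Z transform, similarity to the group
    mean, QC-FC motion correlations and their distance dependence), subject
    inclusion criteria, and a synthetic multi-subject phantom generator with
    known ground truth for end-to-end testing of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    png
Config/testthat/edition: 3
RoxygenNote: 7.3.3
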