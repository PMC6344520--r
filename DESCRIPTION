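Package: motionstack
Title: Stacked-Ensemble Analysis of Head-Motion Predictors in Resting-State fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how much variance in head motion during resting-state
    fMRI is explained by physical versus psychological subject characteristics.
    Computes per-scan motion summaries (mean Euclidean norm and framewise
    displacement of the six rigid-body realignment parameters) from AFNI-style
    .1D files, and estimates predictive R-squared with a stacked ensemble of
    six base learners (elastic net, principal component regression, partial
    least squares, support vector regression, random forest, and a
    conditional-inference-style forest) inside repeated nested cross-validation
    with random-search tuning and the one-standard-error rule. Variable
    importance is aggregated across learners with the stacking weights, and a
    residualization procedure isolates predictor variance not shared with the
    physical block. A latent-factor synthetic cohort generator provides
    ground-truth data for calibration and testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    glmnet,
    ranger,
    e1071,
    mixOmics,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    caret
Config/testthat/edition: 3
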