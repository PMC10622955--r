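Package: brainager
Title: Brain Age Gap Estimation on Synthetic Structural MRI Phantoms
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulates aging-brain structural MRI phantoms with an injectable
    disease-related aging offset, trains a 3D convolutional age regressor with
    a mean-absolute-error stochastic-gradient-descent protocol, computes
    bias-corrected BrainAGE (brain age gap estimation) z-scores referenced to
    a control group, localizes the regressor's evidence with
    occlusion-sensitivity attention maps, and runs the accompanying group
    stratification statistics (effect sizes, age-adjusted comparisons,
    ROC/Youden cutoffs, screened multivariate logistic regression).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    rlang,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    MASS
Config/testthat/edition: 3
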