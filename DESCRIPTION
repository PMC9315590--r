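Package: collat4d
Title: Collateral Circulation Assessment from Dynamic 4D-CTA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulation and analysis pipeline for assessing cerebral
    collateral circulation from dynamic whole-brain CT angiography
    (4D-CTA). Generates labelled synthetic dynamic studies with
    gamma-variate bolus hemodynamics and a graded collateral filling
    deficit; detects the arterial, arteriovenous, venous, and late-venous
    phase landmarks on time-density curves; builds subtracted,
    bone-removed maximum-intensity-projection montages; trains residual
    convolutional network classifiers (single stitched-montage input and
    four-branch late fusion) for dichotomized collateral grading;
    evaluates them with Monte Carlo cross-validation and aggregated ROC
    curves; and computes the cohort baseline comparison statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    png,
    RNifti,
    Rcpp,
    stats,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
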