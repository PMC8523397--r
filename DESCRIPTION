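Package: tibrad
Title: Tibial Bone Radiomics for Knee Osteoarthritis Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, fully synthetic-testable pipeline for distinguishing
    knees without and with MRI-defined tibiofemoral osteoarthritis from radiomic
    features of tibial bone. Provides a knee-phantom generator with MOAKS-consistent
    labels, rule-based MOAKS osteoarthritis definitions, multi-atlas plus
    appearance-model tibia segmentation with Dice evaluation, six-VOI extraction
    below the cartilage-bone interface, a radiomic feature engine
    (shape/orientation/histogram/GLCM/GLRLM/GLSZM/NGTDM/LBP/Gabor), an elastic-net
    logistic classifier with repeated stratified cross-validation and grid search,
    and ROC/PR AUC evaluation with bootstrap confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    ranger,
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
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    pROC,
    optparse
Config/testthat/edition: 3
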