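Package: pathscore
Title: Multi-Scale Convolutional Scoring of Pathway Activation in
    Nuclear-Translocation Reporter Assays
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies signalling-pathway activation of gene variants from
    three-channel fluorescence well images of a nuclear-translocation
    reporter assay. Implements a compact multi-scale, patch-based deep
    convolutional network (with sigmoid activation head and multi-gene
    softmax head), plate-stratified data splitting, seeded training with
    Adam, per-variant aggregation with the 0.5 activity call, Welch
    comparison of variants to wildtype, dose-response series construction,
    ROC/AUC and confusion-matrix evaluation, and a classical
    nuclear-to-cytoplasmic intensity-ratio oracle. A bundled synthetic
    translocation-assay simulator with known ground truth makes the whole
    pipeline runnable and testable without access to proprietary imaging
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    tiff,
    EBImage,
    yaml,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: CellBasedAssays, Classification, Software
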