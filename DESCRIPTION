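Package: zotga
Title: Zone-of-Transition Radiomics with Genetic-Algorithm Feature
    Selection and Leakage-Aware Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for discriminating renal tumor histotypes from CT
    radiomic features. Extracts the peritumoral zone of transition (ZOT)
    from a binary tumor mask by repeated 3D morphological dilation and
    erosion, computes named radiomic feature vectors for tumor and ZOT
    regions through a pluggable extraction engine with a native
    first-order/shape backend, performs genetic-algorithm wrapper feature
    selection with a decision-tree cross-validated ROC AUC fitness, and
    runs paired evaluation experiments ("selection before split" versus
    "selection after split" over repeated stratified train/test splits)
    that quantify the optimism introduced by feature-selection leakage.
    Includes phantom-volume and feature-table simulators so the whole
    pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    graphics,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    rpart,
    pROC,
    ggplot2,
    optparse
Config/testthat/edition: 3
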