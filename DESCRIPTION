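Package: ablaquant
Title: Quantitative Analysis for Sub-Ablative Irreversible Electroporation Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for planning and quantifying sub-ablative high-frequency
    irreversible electroporation (H-FIRE) experiments. Includes a finite
    difference quasi-static conduction solver for paired needle electrodes
    with forward ablation-coverage prediction and inverse lethal-threshold
    estimation; chromogenic immunohistochemistry quantification (H-DAB colour
    deconvolution, maximum-entropy thresholding, area percent and microvessel
    density per region of interest); a lymph-node dual-marker vessel pipeline
    with pixel and object classifiers and the Vascular Complexity Index;
    standard-curve quantification for qPCR (log-linear) and ELISA
    (four-parameter logistic); cohort growth statistics; and seeded synthetic
    data generators with ground-truth sidecars for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    grDevices,
    utils,
    EBImage,
    nnet,
    randomForest,
    minpack.lm,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    tiff,
    withr,
    optparse
Config/testthat/edition: 3
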