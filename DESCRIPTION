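Package: plasmiR
Title: Circulating miRNA Signatures and Neural-Network Classification of
    BI-RADS 4 Breast Lesions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for discovering minimal circulating microRNA signatures
    from qPCR Ct data and classifying suspicious (BI-RADS category 4) breast
    lesions as malignant or benign.  Implements sample quality control
    (hemolysis and RT/PCR-inhibition rules), global-mean and calibrator-based
    2^-dCt quantification, model-based reference-gene stability ranking,
    Mann-Whitney differential representation with FDR control, and a
    from-scratch multilayer perceptron trained with resilient backpropagation
    (iRPROP-) under early stopping, with stochastic topology search over
    stratified train/validation/test splits.  Seeded synthetic cohort
    generators emulate the screening, validation and BI-RADS 4 phases of such
    a study so the whole pipeline is exercisable end-to-end without patient
    data.  Diagnostic performance is summarised by confusion matrices,
    sensitivity, specificity, likelihood ratios and ROC/AUC.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
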