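Package: lfqpanel
Title: Biomarker Panel Discovery for Label-Free Quantitative Proteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end discovery of minimal protein biomarker panels from
    label-free quantitative (iBAQ) proteomics of small three-group clinical
    cohorts. Reads MaxQuant proteinGroups tables, reproduces the Perseus-style
    preprocessing stage (contaminant removal, column-sum normalization, log2
    transform, group-wise validity filtering, per-sample downshifted-normal
    imputation of left-censored missing values), applies distribution-aware
    omnibus and pairwise differential testing with Holm adjustment, ranks
    proteins by exhaustive linear-discriminant subset search, screens
    candidates by Pearson pair correlation and per-protein ROC analysis, and
    evaluates predictive power by repeated stratified k-fold cross-validation
    of multinomial logistic models over protein pairs. Includes a synthetic
    data generator with planted group effects and intensity-dependent
    missingness, and 2^-DeltaDeltaCt relative-expression computation for qPCR
    follow-up.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    car,
    jsonlite,
    nnet,
    stats,
    utils
Suggests:
    MASS,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
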