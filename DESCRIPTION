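Package: npxaging
Title: Biological Aging Proteins from Olink Plasma Proteomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A multi-stage analysis pipeline for Olink NPX plasma proteomics
    that identifies biological Aging Proteins (APs) at the intersection of
    age-group and disease-burden differential expression. Provides
    normality-gated paired/unpaired differential testing with geometric-mean
    fold changes and Benjamini-Hochberg correction, set-intersection protein
    classification with literature-overlap and novel-marker reporting,
    complete-linkage hierarchical clustering with scree-based cluster-number
    selection and subsample Rand-index stability scoring, hypergeometric
    over-representation analysis against stacked gene-set collections, and a
    mortality-signature extraction via stratified LASSO-penalized Cox
    regression with cross-validation and bootstrap stability selection. A
    synthetic-cohort generator with ground-truth labels makes every stage
    testable without access-restricted cohort data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    glmnet,
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
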