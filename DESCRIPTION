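Package: metaboprs
Title: Metabolite and Polygenic Risk Score Interaction Analysis for Glaucoma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how circulating NMR metabolites modify
    polygenic risk of glaucoma. Provides a synthetic cohort generator
    emulating the biobank data structure (a standardized polygenic risk
    score, a block-correlated 168-metabolite panel, clinical covariates and
    a ~4% case prevalence), rank-based probit scoring and median/mode
    imputation, nested penalized logistic prediction models with held-out
    ROC/AUC and DeLong comparisons, discovery of metabolites associated
    with resilience to high genetic risk under an effective-number-of-tests
    (eigenvalue) multiple-testing correction, metabolite risk score
    construction, and quartile-stratified gene-metabolite interaction
    odds-ratio tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    glmnet,
    jsonlite
Suggests:
    pROC,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
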