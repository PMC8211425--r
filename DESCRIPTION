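Package: tmecausal
Title: Tumor-Microenvironment Biomarker Discovery with Targeted Maximum
    Likelihood Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for identifying tumor
    microenvironment (TME) related prognostic biomarkers from bulk tumor
    RNA-seq and clinical data. Computes single-sample immune and stromal
    enrichment scores, performs negative-binomial differential expression
    between score-defined groups, screens candidate genes by univariate
    logistic regression against a binary mortality outcome, selects minimal
    confounder sets via backward conditional-independence elimination, and
    estimates average, individual, and marginal-odds-ratio effects of
    dichotomized gene expression on mortality by targeted maximum likelihood
    estimation with a Super Learner ensemble. Includes a synthetic cohort
    generator with analytically known counterfactual effects so every stage
    is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    glmnet,
    xgboost,
    randomForest,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    pROC,
    withr
Config/testthat/edition: 3
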