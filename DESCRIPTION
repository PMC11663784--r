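Package: radresp
Title: Transcriptomic Prediction of Complete Response to Chemoradiotherapy in Rectal Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-track analysis pipeline for predicting pathological
    complete response (pCR) to neoadjuvant chemoradiotherapy from bulk
    tumour transcriptomes. The hypothesis-based track scores candidate
    gene signatures (stromal TGF-beta response, cytotoxic-lymphocyte
    abundance, molecular-subtype membership), tests them by adjusted
    logistic regression with backward stepwise selection, and combines the
    survivors into a compound biological radiosensitivity score. The
    hypothesis-free track selects robust differentially expressed genes
    over class-balanced subsamples, prunes them to decision-making genes,
    trains and locks a classifier under stratified cross-validation, and
    validates it externally after native empirical-Bayes (ComBat-style)
    batch correction in outcome-supervised or outcome-agnostic mode,
    defended by a random-geneset permutation null and characterised by
    preranked gene-set enrichment and cross-cohort meta-analysis. A
    seeded synthetic-cohort generator with planted immune/stromal signal
    blocks makes every stage testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    Matrix,
    jsonlite,
    base64enc,
    digest,
    glmnet,
    xgboost,
    randomForest,
    e1071,
    nnet,
    pROC
Suggests:
    testthat (>= 3.0.0),
    limma,
    sva,
    metafor,
    fgsea,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
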