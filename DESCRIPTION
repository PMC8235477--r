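Package: omixtask
Title: Multi-Task Variational Embedding of Multi-Omics Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joint low-dimensional embedding of multiple omics profiles
    (gene expression, DNA methylation, miRNA expression) with a variational
    autoencoder, and jointly trained downstream heads for phenotype
    classification, age regression and discrete-time survival prediction
    (multi-task logistic regression over a grid of time intervals).
    Task losses are balanced by gradient-norm weighting and the network is
    trained in three phases: unsupervised embedding pre-training, downstream
    head training on the frozen embedding, and joint fine-tuning. Includes a
    synthetic multi-omics generator with known latent structure, Xena-style
    TSV input/output, stratified splitting and cross-validation, and
    evaluation metrics (macro-averaged classification metrics, regression
    metrics, Harrell's concordance index, Brier score and integrated Brier
    score with inverse-probability-of-censoring weighting).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    survival,
    pROC,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
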