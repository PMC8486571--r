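Package: platimg
Title: Pathway-Panel Image Classification of Platelet RNA-Seq Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Converts platelet RNA-seq count profiles into pathway-panel
    images (one row per curated KEGG-style pathway, one pixel per member
    gene) and classifies them with a small convolutional neural network.
    Implements the full pipeline: read-count sample filtering, gene-name
    mapping, median-of-ratios size factors, a closed-form negative-binomial
    variance-stabilizing transformation with a fitted dispersion-mean trend,
    categorized GMT panel parsing and pruning, image construction with
    global intensity scaling, a seeded from-scratch CNN (two tanh
    convolutions, four relu dense layers, two dropout layers, sigmoid
    output) trained with adadelta and frequency-proportional class weights,
    and a validation harness with stratified hold-out, stratified k-fold
    cross-validation, fold-averaged TEP scores, cross-validated AUC with
    influence-curve confidence intervals, and the full confusion-metric
    suite. A synthetic-cohort generator makes every stage testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    png,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    optparse
Config/testthat/edition: 3
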