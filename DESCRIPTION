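Package: mces
Title: Multi-Class Computational Evolution System for Expression-Based
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evolves symbolic discriminant expressions for multi-class
    classification of gene-expression data by genetic programming. Samples
    are classified by thresholding the scalar output of an evolved
    expression: per-class medians of the training test values are ordered,
    successive medians are averaged into thresholds, and all 2^(n-1)
    inequality-direction combinations are searched exhaustively. Selection
    balances classification accuracy against model complexity (building-
    block count) through a Pareto domination tournament on a toroidal
    solution grid. Includes the accompanying evaluation protocol (repeated
    stratified k-fold cross-validation, balanced and multi-class accuracy,
    Tanimoto feature-set stability), expression-data preprocessing
    (low-count filtering, log2(x+1) transform, one-way F-statistic feature
    pre-ranking), and a synthetic multi-class expression-data generator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
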