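Package: lumisig
Title: Gene-Signature Derivation and Projection for Luminal Breast Cancer
    Expression Studies
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A tested re-implementation of a knockdown-to-cohort expression
    analysis pipeline: two-channel microarray lowess normalization and
    intensity/presence gene filtering, a from-scratch two-class unpaired
    Significance Analysis of Microarrays (SAM) engine with permutation-based
    false discovery rate calibration, inner-product projection of SAM-weighted
    gene signatures onto tumor and mammary-lineage expression profiles,
    node-correlation gene-module extraction from correlation dendrograms with
    signature-overlap decomposition, and expression-stratified Kaplan-Meier /
    log-rank survival association. Seeded synthetic-data generators emulate
    every input shape with known ground truth for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: GeneExpression, DifferentialExpression, Microarray, Survival,
    Clustering
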