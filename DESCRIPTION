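Package: txrewire
Title: Transcriptomic Rewiring Analysis of Drug-Sensitive and
    Drug-Resistant Cancer Cell States
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for characterizing transcriptomic rewiring
    between drug-sensitive and drug-resistant cancer cell states from
    gene-level RNA-seq counts: TMM normalization and log-CPM
    transformation, Welch-t differential expression with fold/significance
    filtering, K-means classification of parental/treated/resistant
    expression patterns into archetypes, hypergeometric and preranked
    running-sum gene-set enrichment, derivation of an interferon-related
    resistance signature with multi-signature overlap analysis, modified
    Z-score signature scoring with Kaplan-Meier/logrank survival
    stratification, and four-parameter-logistic IC50 dose-response
    fitting.  Includes negative-binomial count, survival-cohort, and
    viability-curve simulators with planted truth tables for recovery
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    survival,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    mclust,
    jsonlite
Config/testthat/edition: 3
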