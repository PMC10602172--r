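Package: nkbias
Title: NKG2A/NKG2C Immune Bias Classification and Pan-Disease Association Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rule-based classification of NKG2A+ and NKG2C+ immune biases from
    single-cell, bulk, and spatial transcriptomes, with the downstream statistics
    used to relate those biases to clinical outcomes. Provides absolute-threshold,
    Z-score-margin, bulk pentile, and sparse spatial calling rules; patient-level
    bias assignment with compartment-specific ratio rules; covariate-adjusted
    logistic (log-odds) models; Kaplan-Meier and log-rank survival comparisons;
    hypergeometric set-overlap, Mann-Whitney, and correlation tests; a
    TCR-repertoire-based CMV serostatus classifier (two-feature linear SVM with
    cross-validation); spot-level density diffusion and ligand-receptor product
    scoring for spatial data; and a seeded synthetic-data generator that emulates
    the statistical structure of each input so every stage is testable without
    external cohorts.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    survival,
    e1071,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
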