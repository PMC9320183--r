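Package: methspec
Title: Cancer-Specific DNA Methylation Biomarker Discovery from Beta-Value Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for identifying cancer type-specific DNA
    methylation gene biomarkers from pan-cancer beta-value matrices. Probes are
    mapped to promoter windows, filtered for missingness, KNN-imputed and batch
    harmonized; per-cancer differentially methylated sites are called with
    Welch t-tests and Benjamini-Hochberg correction; characteristic sites are
    selected with a native Boruta implementation; and genes are assigned to
    exactly one cancer type through an entropy and coefficient-of-variation
    based specificity score with a dissociation transform. Downstream stages
    cover random-forest classification, Kaplan-Meier survival screening,
    cross-cohort validation and ridge-regression drug-sensitivity prediction.
    A synthetic-cohort generator with planted ground truth supports testing
    every stage against known answers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    pROC,
    purrr,
    ranger,
    readr,
    rlang,
    rpart,
    stats,
    survival,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
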