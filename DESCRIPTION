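Package: grscart
Title: Two-Stage Candidate-SNP Association, Genetic Risk Scores and CART
    Interaction Analysis for Case-Control Studies
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for two-stage candidate-SNP case-control studies of
    occupational noise-induced hearing loss and similar binary traits:
    genotype and phenotype table import (TSV/CSV and VCF), audiometric case
    definitions (BHFTA, MTWV) and cumulative noise exposure, Hardy-Weinberg
    and call-rate quality control, association analysis under five genetic
    models with crude and covariate-adjusted odds ratios, an unweighted
    genetic risk score with binned dose-response estimation and trend
    testing, classification-tree (CART) analysis of gene-gene and
    gene-environment interactions with terminal-node risk estimation, and a
    synthetic two-stage cohort generator so the full pipeline can be
    exercised without access to individual-level study data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    VariantAnnotation,
    rpart,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
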