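Package: atriskimmune
Title: Cross-Sectional Immune Dysregulation Profiling for ACPA-Positive
    At-Risk Individuals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for cross-sectional immune profiling of
    individuals at risk for seropositive rheumatoid arthritis across three
    participant groups (ACPA-negative controls, ACPA-positive at-risk, and
    early RA). Implements differential DNA-methylation calling with
    two-cohort hypergeometric replication, promoter/gene-body mapping to
    differentially methylated genes, pathway over-representation, and
    one-vs-one random-forest group classification; tetramer-based
    antigen-specific CD4+ T-cell frequency statistics; a
    metaclustering-based cytometry phenotype landscape with per-subject
    z-score profiles and aligned-cluster group comparisons; antibody-array
    positivity calling and covariate-adjusted group models with FDR
    control; and baseline cohort comparisons. Includes a synthetic-data
    generator that emulates all three input kinds with planted,
    configurable group effects so every stage is testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    igraph,
    randomForest,
    rlang
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    glmnet,
    fgsea
Config/testthat/edition: 3
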