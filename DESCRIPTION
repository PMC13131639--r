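Package: synoclust
Title: Consensus Clustering and Cartilage-Degeneration Analysis of Synovial Transcriptomes
Version: 0.1.0
Authors@R:
    person("RE-JOIN", "Analytics", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for molecular subtyping of osteoarthritis
    synovium from bulk RNA-seq and for linking synovial gene expression to
    cartilage degeneration severity. Implements resampling-based consensus
    clustering with CDF/delta-AUC model selection, prevalence-thresholded
    single-cell marker derivation, rank-based differential expression with
    Benjamini-Hochberg control, signed per-cell module scores with KNN
    smoothing, preranked and single-sample gene-set enrichment, and spatial
    zoom-region enrichment statistics (Fisher's exact test, fold enrichment).
    Ships synthetic-cohort generators so every stage is testable end-to-end
    without access to deposited patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Matrix,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
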