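Package: screensift
Title: Plate-Based RNAi Screen Analysis: Normalization, Quality Control,
    Hit Calling and Gene-Centric Mining
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for arrayed RNAi screens read out in
    multi-well plates. Ingests well-level screen tables from CSV with
    plate/well/control annotations, applies plate-local normalizations
    (log, Z score, control-based scores and fold change, and B scores
    from a two-way median polish), computes assay quality metrics
    (Z-prime factor over control pairs, replicate correlation), supports
    threshold-based hit calling and siRNA deconvolution (multi-reagent)
    validation, and mines hit lists against local Gene Ontology and
    protein-protein interaction snapshots (Fisher's exact enrichment,
    term search and exclusion, subnetwork extraction with SIF export).
    Includes seeded generators for synthetic screens, annotations and
    interaction stores with planted ground truth, so every pipeline
    stage can be validated without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
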