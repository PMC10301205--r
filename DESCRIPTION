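Package: dynetox
Title: Dynamic Co-Occurrence Network Models for Developmental Toxicology
    Endpoints
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Builds time-indexed weighted co-occurrence networks from
    longitudinal binary abnormality records in developmental toxicity
    studies (e.g. daily scoring of zebrafish embryos for pericardial
    edema, yolk sac edema, cranial malformation, spinal deformity,
    delayed swim bladder inflation and mortality). Pairwise associations
    are measured per exposure group and day with two-sided Fisher exact
    tests computed from first principles, converted to link weights
    w = 100*(1-p), and assembled into per-day adjacency matrices. Degree
    and eigenvector centrality, the spectral radius, critical-node
    tables with tie handling, and node-importance summaries describe how
    abnormality co-occurrence develops over time and across exposure
    levels. A survival-bias-aware synthetic cohort simulator with
    concentration- and time-dependent incidence, shared frailty, driver
    coupling and absorbing mortality makes every stage testable without
    external data. Includes command-line style entry points for
    simulation, analysis and reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    pheatmap,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
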