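Package: cytoconsensus
Title: Consensus Population Identification for Heterogeneous Flow Cytometry Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for flow cytometry of heterogeneous cell
    populations measured with a small marker panel and non-optimized controls.
    Provides bead-anchored two-point batch normalization, sequential
    quantile-based gating with a gate-placement variation study,
    multi-algorithm high-dimensional clustering (self-organizing map
    metaclustering, shared-nearest-neighbour community detection, density-peak
    assignment) with 2-D embeddings, co-association consensus population
    identification anchored on single-stain bead controls, and
    probability-binning chi-squared T(x) statistics with control-adjusted
    significance and passage-resolved population tables. Includes a synthetic
    study generator emulating a two-day, two-passage lymph-node stromal cell
    experiment for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    RANN,
    Rtsne,
    igraph,
    matrixStats,
    stats,
    tools,
    utils,
    uwot
Suggests:
    cluster,
    jsonlite,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
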