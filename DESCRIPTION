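Package: tripnet
Title: Tripartite Microbe-Brain-Phenotype Correlation Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates gut microbial genus abundances, functional brain-network
    centrality, and gastrointestinal sensorimotor phenotypes into tripartite
    correlation networks. Computes covariate-adjusted (partial) Spearman
    correlations within subject groups, contrasts them between groups with the
    Fisher r-to-z difference test, builds group and difference networks,
    extracts genus-centred first-neighbour subnetworks, and classifies direct
    versus indirect (two-step, via a brain node) associations. Includes a
    Gaussian-copula cohort simulator with planted cross-block correlations for
    calibration and power studies, weighted graph centrality measures (degree
    strength, betweenness, eigenvector) for region-by-region connectivity
    matrices, genus missingness filtering, cohort-level descriptive statistics,
    sensitivity (minimal detectable correlation) analysis, and
    Cytoscape-compatible GraphML and SIF export.
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
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
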