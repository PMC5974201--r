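Package: netage
Title: Co-Expression Modules and Differential Protein-Interaction
    Connectivity Across Brain Aging and Alzheimer's Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds signed weighted gene co-expression networks from
    normalized hippocampal expression profiles of young, aging and
    Alzheimer's disease (AD) groups, detects modules by topological
    overlap and tree cutting, summarizes them by SVD eigengenes,
    trait correlations, cell-type marker enrichment and permutation
    Z-summary preservation statistics, and overlays condition-specific
    expression on a protein-protein interaction network to detect
    differentially connected edges via weighted edge-betweenness
    centrality, extracting up- and downregulated subnetworks with
    degree-ranked hub genes. Includes a synthetic-data generator with
    planted modules and perturbed interactions so every stage can be
    benchmarked against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    mclust,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    tidyr,
    utils
Suggests:
    limma,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
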