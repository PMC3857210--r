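Package: netcondense
Title: Differential Network Condensation and Active Subnetwork Mining for
    Two-Group Expression Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Maps two-group gene expression data onto a confidence-filtered
    protein interaction network and extracts the interactions that change
    most between the groups. Implements per-edge link scores (log2 fold
    change of the product of endpoint group means), condensation to the k
    most up- and down-regulated interactions, per-case indicator matrices,
    and K/L-constrained maximal connected active-subgraph extraction
    (individual-node-exception semantics) with exact and greedy solvers.
    Includes interaction- and gene-level significance testing with
    Benjamini-Hochberg adjustment, hypergeometric over-representation
    analysis of result gene sets, and a synthetic-data generator with
    planted differentially regulated edges and controllable responder
    heterogeneity for benchmarking.
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
    limma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
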