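Package: xenoscan
Title: Dated Gene-Tree Reconciliation and Synteny Association Scanning for Gene Family Evolution
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reconstructing the evolutionary history of fungal gene
    families such as the nonreducing polyketide synthases. Implements dated
    duplication-transfer-loss (DTL) maximum-parsimony reconciliation of gene
    trees against a chronogram, with exact counting and uniform sampling of
    co-optimal reconciliations, event-support profiling across a transfer-cost
    grid, and robustness-flagged transfer calls. Adds Markov clustering of
    homolog similarity graphs into candidate homolog groups, a Fisher-exact
    clade-association scan over gene neighborhoods with Bonferroni correction
    and local-minimum reporting, neighborhood-retention statistics by event
    type, and exon-junction mapping onto alignment consensus coordinates.
    Includes a full synthetic-data generator (birth-death chronograms, DTL
    gene families with recorded true events, genomic neighborhoods with
    event-dependent synteny decay, gene structures, and block-structured hit
    tables) for end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    dplyr,
    purrr,
    tibble,
    rlang,
    readr,
    igraph,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    cluster
Config/testthat/edition: 3
RoxygenNote: 7.3.3
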