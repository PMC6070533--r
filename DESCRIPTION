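Package: s2b
Title: Double Specific Betweenness for Predicting the Overlap of Network Modules
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Predicts which nodes of an interaction network belong to the
    overlap of two network modules (for example the disease modules of two
    phenotypically related diseases) when only incomplete seed sets for each
    module are known. Implements the S2B score, the fraction of retained
    short(est) paths linking one seed set to the other that pass through a
    node, together with its L-curve score threshold and two randomization
    based specificity scores (random seed sets and degree-preserving rewired
    networks). Ships an artificial-module benchmark suite (shell,
    connectivity-significance and random-walk-with-restart module models on a
    scale-free surrogate network), a re-implementation of the DIAMOnD
    iterative module-expansion baseline, and structural analysis of the
    candidate subnetwork (maximal cliques, clustering of candidates by
    co-occurrence on retained shortest paths).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    Rcpp,
    stats,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
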