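Package: prunewave
Title: Phylogenetic Likelihood Engine with Wavefront Traversal Scheduling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A buffer-based engine for phylogenetic likelihood computation
    under reversible substitution models (JC, HKY, GTR, and arbitrary rate
    matrices) with discretized-gamma rate heterogeneity. Implements the
    pruning algorithm over compressed, weighted site patterns; partitioned
    evaluation of independent data subsets within a single shared engine
    instance; reverse level-order ("wavefront") scheduling of partial
    likelihood operations with optional rerooting to raise concurrency;
    per-pattern numerical rescaling for large trees; analytic first and
    second branch-length derivatives of the log-likelihood; a sequence
    simulator for fully synthetic test data; and automatic selection of
    the fastest compute kernel by benchmarking on the problem at hand.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ape,
    seqinr,
    Matrix,
    stats,
    utils,
    parallel,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
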