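Package: angionet
Title: Synchronous Boolean Network Analysis of Endothelial Cell Behavior
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and exhaustively analyzing synchronous Boolean
    models of molecular regulatory networks, centered on a bundled 64-node
    model of endothelial cell (EC) behavior during sprouting angiogenesis.
    Provides a BoolNet-dialect text parser and writer, exact attractor
    enumeration (brute force for small state spaces and a binary decision
    diagram backend for larger clamped cores), classification of attractors
    into Tip, Stalk and Phalanx EC behaviors from marker signatures, an
    exhaustive sweep over all 65,536 extracellular micro-environments,
    attractor-preserving network reduction operators, in-silico gain- and
    loss-of-function mutation scans, Monte-Carlo robustness estimation under
    single-bit activation noise, and per-rule Boolean sensitivity analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    withr,
    jsonlite,
    ggplot2,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
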