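Package: mtpgraph
Title: Graphical Multiple Testing Procedures with Exact Epsilon-Edge Arithmetic
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Sequentially rejective graphical multiple testing procedures for
    confirmatory clinical trials, with hypothesis weights and edge fractions
    kept as exact rationals optionally carrying a symbolic infinitesimal
    epsilon, so that epsilon-edge procedures are evaluated in the limit
    epsilon -> 0+ rather than with a small floating-point stand-in. Includes
    preset graphs for a three-arm (two doses vs active control), two-endpoint
    non-inferiority/superiority Phase III design (gatekeeping, cross-dose
    alpha recycling, epsilon-edge, and direct-path variants), a two-hypothesis
    Hochberg test, fixed-margin (95-95) non-inferiority margin construction
    from a random-effects meta-analysis of historical trials, and a Monte
    Carlo harness estimating family-wise error rate and power.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    metafor,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
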