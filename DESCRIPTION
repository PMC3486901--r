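Package: mitoreticulum
Title: Fission-Fusion Dynamics of the Mitochondrial Reticulum
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Graph-based modelling of the cell-wide mitochondrial network
    (chondriome) shaped by tip-to-tip and tip-to-side fusion and fission.
    Provides an exact Gillespie simulator on a dynamic graph whose nodes are
    restricted to degrees 1-3, a mean-field steady-state solver linking the
    fusion/fission rate ratios to network morphology, master equations for
    the loop/open-segment length distributions of the tip-to-tip-only
    network, segment and cluster censuses with geometric and negative
    binomial size laws, percolation-transition analysis via the
    susceptibility peak, and a skeleton-image branch-point census with
    confocal-overlay correction.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    jsonlite,
    png,
    tiff,
    tools,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
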