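Package: polarquart
Title: Polarized Quartet Support and Rooted Clade-Tree Ranking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quartet-based evaluation of rooted phylogenetic hypotheses among
    predefined clades. For every species-quartet (one outgroup sequence plus
    one sequence from each of three ingroup clades) the package counts
    polarized split-supporting site patterns, corrects them for the number of
    convergent patterns expected under the competing topologies (estimated by
    quartet maximum likelihood under a GTR-family model), and normalizes the
    result into relative topology supports. Signal-to-noise (RISK) and
    signal-distance (DIST) filters with uphill-climbing threshold optimization
    remove unreliable quartets; retained supports are aggregated per
    clade-quartet by medians and translated into a pairwise-compatibility
    support matrix that scores and ranks every rooted tree of the ingroup
    clades. A sequence simulator with Lavalette-distributed indels is included
    for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    ape,
    Rcpp,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    phangorn,
    Matrix,
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
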