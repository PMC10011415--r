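Package: hypercontagion
Title: Critical-Mass Social Contagion Dynamics on Hypergraphs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying binary-state critical-mass contagion on hypergraphs:
    statistically exact continuous-time (Gillespie) simulation with a quasi-stationary
    sampling method for absorbing-state dynamics, an individual-based mean-field ODE
    system built on the Poisson-binomial distribution evaluated through its discrete
    Fourier transform, structured hypergraph generators (random-regular "hyperblob",
    two-community model with bridge hyperedges, vertex-labeled configuration-model
    rewiring), and the exact occupancy Markov chain of the hyperblob used to
    characterise hybrid phase transitions, multistability and intermittency.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Matrix,
    igraph,
    deSolve,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
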