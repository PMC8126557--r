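Package: transamp
Title: Transient Amplifiers of Selection Constructed from Regular Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects which small k-regular graphs become transient amplifiers
    of selection under death-birth updating when an edge is removed at the
    vertex of largest remeeting time.  Provides exhaustive enumeration of
    connected pairwise nonisomorphic regular graphs, coalescing-random-walk
    machinery (pairwise coalescence times, remeeting times, effective
    population size), the edge-removal perturbation test for amplifier
    constructors, exact fixation probabilities for death-birth updating via
    the absorbing Markov chain, normalized-Laplacian spectral summaries
    (spectral gap, smoothed spectral density, spectral distance, von Neumann
    entropy, Kesten-McKay reference density), a threshold classifier for
    pre-selecting amplifier constructors, and a census pipeline tying the
    stages together.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    Matrix,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
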