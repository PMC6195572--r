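Package: markovcp
Title: Multiscale Markov Models with Change Points for Temporal Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models temporal contact networks as sequences of edge activations
    drawn from arbitrary-order Markov chains whose transition probabilities
    switch abruptly at change points. Provides Dirichlet-multinomial marginal
    likelihoods for Bayesian selection of the Markov order, Metropolis-Hastings
    sampling of change-point segmentations with split/merge/shift moves,
    surrogate sequence generation from fitted models, discrete-time SIR/SIS
    epidemic simulation driven by the edge sequence, inter-event (waiting-time)
    diagnostics, and a planted-model benchmark generator for end-to-end
    recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
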