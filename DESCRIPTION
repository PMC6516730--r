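Package: smcdecode
Title: Sequential Monte Carlo Decoding of Stochastic Stimuli from Leaky
    Integrate-and-Fire Spike Trains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Encode-decode framework for neural spike trains under the
    probability-mixing model of visual attention.  Simulates spike trains
    from a leaky integrate-and-fire neuron with a spike-response kernel
    whose input switches, following a Markov chain, between the components
    of a mixture of Ornstein-Uhlenbeck stimuli.  Decodes the stochastic
    stimulus paths and the stimulus parameters with sequential Monte Carlo
    particle filters (bootstrap and auxiliary, with and without
    marginalised attention), Liu-West kernel-smoothed parameter learning,
    fixed-lag and forward-filtering backward-smoothing, and population
    decoding under serial or parallel attention.  Interval likelihoods are
    first-passage-time probabilities obtained by solving the cumulative
    Fokker-Planck equation with a Crank-Nicolson scheme.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
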