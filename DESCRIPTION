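Package: connectr
Title: Monosynaptic Connectivity Inference from Parallel Spike Trains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for inferring monosynaptic connections and postsynaptic
    potential (PSP) amplitudes from pairs of sorted spike trains. Implements a
    conductance-based network simulator of multi-timescale adaptive threshold
    (MAT) neurons with log-normal excitatory and normal inhibitory synaptic
    weights and Ornstein-Uhlenbeck background conductances, cross-correlogram
    construction with shadowing-artifact trimming and time-rescaling
    augmentation, a small one-dimensional convolutional network (CoNNECT)
    mapping a correlogram to connection probability and PSP amplitude, a
    generalized linear model fit to cross-correlograms (GLMCC) with a
    likelihood-ratio significance test, and evaluation utilities (Matthews
    correlation coefficient, duration curves, excitatory-inhibitory dominance
    index).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    yaml,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
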