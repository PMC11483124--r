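Package: repool
Title: Reverse Engineering Synaptic Inputs from Motoneuron Pool Firing
    Patterns
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates a pool of conductance-based spinal motoneurons
    driven by combinations of excitatory, inhibitory and neuromodulatory
    input, finds by closed-loop iteration the excitatory command that
    makes the pool's cumulative spike train match a triangular reference,
    extracts motor-unit firing-pattern features (recruitment timing,
    firing-rate saturation, delta-F hysteresis, brace-height), and
    regresses those features back onto the inputs to quantify how well
    firing patterns identify their synaptic drive. Includes a grid runner
    for embarrassingly parallel parameter sweeps and regression/feature
    ranking tools (linear, shrinkage and support-vector models; stepwise
    F-statistic and mutual-information rankings).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    parallel,
    Rcpp,
    glmnet,
    e1071
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
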