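Package: dynelnet
Title: Dynamic Elastic-Net Estimation of Hidden Inputs in ODE Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates structural model error in ordinary differential
    equation models of biochemical networks from time-course output data.
    Model error is represented as time-varying hidden inputs acting on the
    state variables and recovered by solving an elastic-net regularised
    optimal-control problem (weighted output misfit plus combined L1/L2
    functional penalties on the hidden inputs). The sparse estimate
    localises the state variables targeted by model error, and the observer
    system yields bias-corrected state estimates. Includes built-in
    signalling-pathway and network-motif models, SBML import/export, a
    synthetic ground-truth benchmark generator, error localisation by
    area-under-curve ranking with thresholding-and-refit, an
    alternative-solution heuristic for unobservable errors, and
    noise/parameter robustness studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    compiler,
    deSolve,
    jsonlite,
    stats,
    tools,
    utils,
    xml2,
    yaml
Suggests:
    Matrix,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
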