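Package: magstim
Title: Magnetic Stimulation of Compartmental Neuron Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates magnetic stimulation of neurons by a current-pulsed
    circular coil. Computes the induced electric field of a planar coil from
    the closed-form loop vector potential (complete elliptic integrals) or by
    line-integral quadrature for arbitrary coil paths, models the stimulator
    as a series RLC discharge (overdamped and underdamped), injects the
    induced per-segment currents into a branched compartmental cable model
    with Hodgkin-Huxley excitability, and provides threshold-search and sweep
    protocols: magnetic and current thresholds, activating-function
    diagnostics, action-potential initiation-site localization, and
    strength-duration, coil-position, morphology and neuronal-state
    experiments. Morphologies are read from SWC files or produced by built-in
    geometry builders.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    pracma,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite,
    optparse
Config/testthat/edition: 3
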