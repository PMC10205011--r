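Package: stimnet
Title: Noise and Network Structure in Whole-Brain Stimulation Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulation and analysis of focal stimulation in a delay-coupled
    stochastic Wilson-Cowan whole-brain network model. Provides a synthetic
    structural-connectome generator with distance-dependent weights and
    subcortical hubs, an Euler-Maruyama integrator with conduction delays and
    additive Gaussian noise, Welch power-spectrum and peak-frequency metrics,
    functional connectivity by maximum lagged cross-correlation, the
    functional and structural stimulation-effect statistics, and pipeline
    drivers for coupling sweeps, noise-by-site stimulation grids,
    degree-association statistics with FDR correction, structure-frequency
    similarity, and cognitive-system summaries.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    pracma
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
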