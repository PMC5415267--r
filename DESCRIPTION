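Package: mesopop
Title: Stochastic Mesoscopic Population Dynamics of Spiking Neural Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Two-level simulation of interacting populations of generalized
    integrate-and-fire (GIF) neurons with escape noise. Provides a microscopic
    reference simulator (neuron-by-neuron network with fixed in-degree random
    connectivity), an intermediate binomial survival-number process, and a fast
    stochastic mesoscopic integrator that evolves finite-size population
    activities from expected rates via quasi-renewal refractory densities,
    survival/variance moment equations and a variance-weighted effective firing
    probability. Includes analysis tools (population power spectra, renewal
    theory spectra, interspike-interval statistics, PSTH, dominance-time
    statistics of bistable networks) and turn-key presets for uncoupled,
    adapting, excitatory-inhibitory, winner-take-all and eight-population
    cortical-column models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    graphics,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
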