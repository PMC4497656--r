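Package: diffhomeo
Title: Diffusive Homeostatic Intrinsic Plasticity in Spiking Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates recurrent networks of conductance-based leaky
    integrate-and-fire neurons in which intrinsic excitability is regulated
    homeostatically by nitric oxide (NO), a gaseous messenger that diffuses
    freely through tissue. Spiking drives calcium influx, sigmoidal nNOS
    activation and NO synthesis; NO spreads by explicit finite-difference
    diffusion with decay on a periodic two-dimensional sheet and feeds back
    on each neuron's firing threshold. The package contrasts this diffusive
    homeostasis with canonical non-diffusive (cell-autonomous) homeostasis
    and with randomly assigned homeostatic targets, optionally combined with
    additive spike-timing-dependent plasticity on recurrent excitatory
    synapses. A dynamic mean-field model based on the Ricciardi transfer
    function reduces diffusive signalling to a single local/global mixing
    parameter. Experiment drivers reproduce steady-state firing-rate
    heterogeneity, input-difference persistence, response-linearity,
    input-tracking and orientation-decoding protocols at configurable scale,
    together with the derived metrics (rate-distribution moments, linear
    response R-squared, signal-to-noise persistence time, tracking RMS
    error, population-vector decoding and spike-train statistics).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp (>= 1.0.0),
    pracma,
    stats
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
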