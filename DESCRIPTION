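Package: memhh
Title: Volatile Memristor Emulation of the Hodgkin-Huxley Potassium Channel
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Compact model of volatile oxygen-vacancy memristors (NbOx, WOx)
    and tools to evaluate them as drop-in replacements for the Hodgkin-Huxley
    potassium channel. Provides the device law (Schottky plus tunneling
    conduction with a first-order volatile state), analytic steady states and
    time constants, a canonical squid-axon Hodgkin-Huxley simulator, a hybrid
    neuron in which the potassium channel is replaced by the scaled memristor,
    a resistively coupled multi-compartment axon, two-stage device calibration
    from pulse-train characterisation data, a CMA-ES search over
    voltage/time/current scaling factors, spike and energy analytics, and
    generators of synthetic device-characterisation experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    graphics,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
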