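Package: neohaem
Title: Lumped-Parameter Simulation of Preterm Neonatal Cerebral
    Haemodynamics and Oxygen Metabolism
Version: 0.1.0
Authors@R:
    person("neohaem", "developers", email = "neohaem@example.org",
           role = c("aut", "cre"))
Description: A self-contained lumped-parameter model of cerebral blood
    flow, oxygen transport and cytochrome-c-oxidase redox state in the
    preterm neonatal brain. Simulates stimulus-evoked functional
    activation driven by a haemodynamic response function and produces
    the observables of functional near-infrared spectroscopy (changes in
    oxy-, deoxy- and total haemoglobin and in oxidised
    cytochrome-c-oxidase) together with cerebral blood flow, oxygen
    consumption and blood volume. Includes steady-state autoregulation
    analysis, a registry of stimulus scenarios, least-squares fitting of
    stimulus amplitudes to measured traces, and a synthetic-trace
    generator for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
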