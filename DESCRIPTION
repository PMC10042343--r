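Package: lvhpr
Title: Host-Nested Parasite Lotka-Volterra Dynamics with Energy-Regulated
    Virulence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates host-nested parasitism: a host population carrying a
    parasite that is itself parasitized by a hyperparasite (e.g. a prokaryote
    and its phage living on a common host).  Implements Lotka-Volterra
    dynamics with logistic habitat restriction, encounter-scaled infection
    rates, energy-dependent virulence switching through a two-threshold
    hysteresis relay (with an optional smooth-step interpolation),
    hyperparasite degeneration, and the coupled one-energy/one-pair and
    two-energy/three-pair homeostasis systems.  Closed-form equilibria are
    provided as analytic oracles, together with a hybrid event-driven
    integrator, scenario presets, parameter sweeps, and Malthusian fitness
    statistics for quasispecies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
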