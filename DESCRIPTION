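Package: capfit
Title: Lumped-Parameter Capillary Circuit Modelling and Particle Swarm
    Identification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling capillary microcirculation as a two-state
    lumped-parameter (Windkessel-type) electrical-analogue circuit and for
    identifying its four components (two resistances, an inertance and a
    compliance) from pulsatile flow waveforms by particle swarm optimization.
    Includes Poiseuille-law haemodynamic calculators driven by the
    ankle-brachial index (ABI), synthesis of systolic pulse waveforms,
    state-space simulation with transfer-function extraction, Routh-Hurwitz
    and pole-based stability analysis, ISE/ITSE error objectives, and a
    known-circuit validation bench for parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    Matrix,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
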