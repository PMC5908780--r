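Package: hfovbench
Title: Bench Simulation and Analysis of Bias-Flow Effects on Ventilation
    Efficiency During High-Frequency Oscillatory Ventilation
Version: 0.1.0
Authors@R:
    person("Bench", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates an adult high-frequency oscillatory ventilation
    (HFOV) bench: a sinusoidal oscillator driving a well-mixed 20-L test
    lung with continuous CO2 insufflation, with per-cycle dilution of
    rebreathed gas by the circuit bias flow. Reimplements the matching
    measurement chain: expiratory stroke volume by digital integration of
    a 200-Hz flow signal, steady-state CO2 mass-balance estimation of
    alveolar ventilation, ventilation-efficiency indices, bias-flow
    dilution and rebreathing relations, linearized power and exponential
    curve fits, and one-way ANOVA with Tukey's HSD. Includes a seeded
    synthetic-data generator so the full pipeline is testable without
    hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
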