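Package: phloemclock
Title: Circadian-Gated Starch Metabolism, Phloem Transport and Sink Growth
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates whole-plant carbon dynamics for an Arabidopsis-like annual:
    a sucrose-entrained circadian phase oscillator gates transitory starch
    degradation in source leaves, sucrose is loaded into a six-component phloem
    network and translocated by Muench pressure flow (Hagen-Poiseuille fluxes),
    and the shoot and root apical meristems consume unloaded sucrose for
    respiration and saturating growth. Provides fixed-step fourth-order
    Runge-Kutta integration with dawn/dusk phase resets, photoperiod and
    photoperiod-shift protocols for three plant types (wild type,
    sugar-insensitive mutant, homeostatic ideal), per-photoperiod optimization
    of the clock-gated starch degradation rate, least-squares estimation of the
    growth consumption kinetics from fresh-weight time courses, and a synthetic
    growth-data generator for end-to-end parameter-recovery experiments.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    ggplot2,
    optparse,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
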