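Package: ecpella
Title: Closed-Loop Lumped-Parameter Simulation of ECPELLA Haemodynamics
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A closed-loop, zero-dimensional (lumped-parameter) model of the
    systemic and pulmonary circulations built from 5-element
    resistance-capacitance networks and four time-varying-elastance cardiac
    chambers with unidirectional Bernoulli valves. Simulates mechanical
    circulatory support with VA-ECMO (continuous veno-arterial bypass flow),
    an Impella-class percutaneous axial pump driven by per-level
    head-capacity curves with a left-ventricular suction limiter, and
    VV-ECMO as an arterial-saturation modifier. Provides a fixed-step
    Runge-Kutta engine, beat segmentation and steady-state extraction,
    pressure-volume loop analytics (stroke work, pressure-volume area),
    global oxygen delivery (DO2) calculations, protocol sweeps over pump
    settings in left-ventricular and biventricular failure with or without
    pulmonary hypertension, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
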