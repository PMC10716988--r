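Package: fontansim
Title: Lumped-Parameter Simulation of Mechanical Dyssynchrony in the
    Fontan Circulation
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Zero-dimensional (lumped-parameter) closed-loop model of the
    single-ventricle (Fontan) circulation with a two-compartment
    time-varying-elastance ventricle, for studying mechanical dyssynchrony
    and discoordination. Simulates periodic steady-state hemodynamics with
    a compiled fixed-step integrator, synthesizes hemiglobal longitudinal
    strain curves from a hemispherical ventricular geometry, computes
    discoordination indices (systolic rebound-stretch ratio, time-to-peak
    delay), sweeps activation delay against the delayed-wall volume ratio,
    fits second-order response surfaces to clinical-style indices, and
    generates reproducible synthetic patient cohorts for testing the
    clinical analysis layer.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    yaml
LinkingTo: Rcpp
Suggests:
    deSolve,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE, load = "installed")
RoxygenNote: 7.3.3
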