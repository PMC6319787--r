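Package: rotoranchor
Title: Rotor Dynamics and Dynamical Anchoring in Fibrotic Ventricular Tissue
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Discrete monodomain simulation of two-dimensional human
    ventricular tissue (ten Tusscher-Panfilov 2006 ionic model) with
    gap-junction coupling, probabilistic diffuse fibrosis and
    fibrosis-dependent ionic remodeling. Provides synthetic fibrotic-scar
    generators, S1S2 rotor initiation and conduction-velocity protocols,
    phase-singularity detection and tracking, outcome classification of
    re-entrant activation patterns (termination, anchoring, multi-armed
    rotors), and dipole-source pseudo-ECG computation, for in-silico
    studies of how fibrotic scars restructure and anchor distant rotors.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite,
    optparse,
    ggplot2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
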