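Package: mtp06
Title: Bifurcation and Afterdepolarization Analysis of Modified
    ten Tusscher-Panfilov Human Ventricular Myocyte Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and dynamical-systems analysis of the mid-myocardial
    (M) cell version of the ten Tusscher-Panfilov 2006 human ventricular
    myocyte model and two modified variants (mTP06a, mTP06b) used to study
    phase-2 early afterdepolarizations (EADs) in long-QT syndrome.  Provides
    the 19-variable ionic model with configurable conductance scalings and
    clamping, paced action-potential simulation with per-beat feature
    extraction, EAD detection and behavior classification, equilibrium and
    limit-cycle bifurcation analysis of the non-paced cell, slow-fast
    decomposition of EAD initiation and termination, voltage-clamped
    intracellular calcium subsystem analysis including spontaneous
    sarcoplasmic-reticulum calcium release detection, and one- and
    two-parameter phase diagrams of paced-cell behavior.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
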