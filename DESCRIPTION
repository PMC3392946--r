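Package: fsneuron
Title: Conductance-Based Model of Striatal Fast-Spiking Interneurons with
    Calcium Buffering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of a single-compartment Hodgkin-Huxley
    type model of the striatal fast-spiking (FS) interneuron. The model couples
    six ionic currents (fast transient Na+, Kv1 and Kv3 delayed rectifiers,
    small-conductance Ca2+-activated K+ (SK), high-voltage-activated Ca2+, and
    leak) to a submembrane calcium shell with parvalbumin-like Ca2+/Mg2+
    competitive buffering or generic fast/slow single-site buffers. Provides a
    fixed-step fourth-order Runge-Kutta integrator with current-clamp stimulus
    protocols, spike-train and calcium-transient analysis (firing frequency,
    interspike calcium envelopes, buffer occupancy, SK-current amplitudes),
    and bifurcation tooling (equilibrium continuation, Hopf detection by
    Jacobian eigenvalues, saddle-node of limit cycles by simulation bisection)
    for characterising class-2 excitability and its regulation by calcium
    buffer concentration.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
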