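Package: dscflair
Title: Direct Signal Control for 3D Fast Spin Echo FLAIR at 7 Tesla
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and design of dynamically RF-shimmed 3D fast spin
    echo (FSE) FLAIR sequences for ultra-high-field parallel transmission.
    Provides a spatially resolved extended phase graph (EPG) forward model of
    a long variable-flip-angle echo train under per-pulse multi-channel
    transmit weightings, Bloch simulation of the T2-preparation and adiabatic
    inversion module, and a power-constrained optimal-control optimization
    (direct signal control, DSC) that drives predicted echo amplitudes toward
    an ideal spatially uniform target. Includes static magnitude-least-squares
    shimming and quadrature baselines, universal (multi-subject) solutions,
    synthetic 8-channel head field maps for end-to-end testing, and signal
    homogeneity metrics.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    graphics,
    grDevices,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
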