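Package: wcnet
Title: Delay-Coupled Wilson-Cowan Cortical Networks with Inhibitory
    Synaptic Plasticity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of whole-cortex networks of
    Wilson-Cowan neural masses coupled through a structural connectome with
    axonal conduction delays and driven by interpolated Gaussian noise.
    Implements online inhibitory synaptic plasticity (ISP) that homeostatically
    drives each region's excitatory activity towards a target rate, a
    fixed-step fourth-order Runge-Kutta delay integrator with a staged ISP
    protocol, isolated-unit fixed-point and Hopf bifurcation analysis, and an
    MEG-style functional connectivity pipeline: band-pass filtering, symmetric
    multivariate leakage-correction orthogonalisation, Hilbert envelopes and
    phases, amplitude envelope correlation, phase locking value, phase lag
    index, Kuramoto synchrony and metastability, FC similarity scoring and
    leave-one-out individual-variability Z-scores, and E/I-balance
    diagnostics. Includes generators for synthetic connectomes and surrogate
    per-subject FC sets so the full pipeline is testable without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
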