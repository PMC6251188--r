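Package: fibwave
Title: Wavefront Dynamics Analysis for Cardiac Optical Mapping Movies
Version: 0.1.0
Authors@R:
    person("fibwave", "maintainers", email = "fibwave@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for fibrillation wavefront dynamics in gridded
    optical-mapping voltage movies: signal conditioning (mask-aware spatial
    binning, dominant-frequency mapping, zero-phase FIR band-pass, drift
    removal, normalization), instantaneous phase via envelope normalization
    and the Hilbert transform, phase-singularity detection by topological
    charge with tracking and rotor classification, isophase-based detection
    and classification of new wavefronts, density and frequency maps, and
    a mechanism classifier (rotor-sustained versus new-wavefront-sustained
    fibrillation). Includes synthetic generators of ground-truth movies:
    analytic spiral phase films, quiescence-guaranteeing focal sources,
    a two-variable excitable-media reaction-diffusion solver, and a coupled
    two-layer breakthrough simulator with fibrosis and repolarization
    heterogeneity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
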