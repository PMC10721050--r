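Package: peptrecon
Title: Velocity Profile Reconstruction for Positron Emission Particle Tracking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An in-silico workbench for reconstructing pulsatile arterial
    velocity profiles from sparse tracer-particle data, as acquired by
    positron emission particle tracking (PEPT). Provides analytic pulsatile
    flow fields on parametric stenosed-tube and coronary-bifurcation
    geometries (a computational-fluid-dynamics stand-in with optional
    post-stenotic recirculation), a lumped-parameter (Windkessel) outlet
    pressure model with calibration, Stokes-number tracer fidelity analysis,
    a ballistic Lagrangian particle tracker with plane-of-interest crossing
    extraction, direct random sampling of the flow at a cross-section, and
    space-time universal kriging with an anisotropic exponential
    semivariogram, no-slip boundary augmentation and kriging-variance
    uncertainty maps. Includes the error metrics used to score
    reconstructions (normalized RMS profile error, peak-velocity error,
    area-averaged velocity curve error, particle clustering) and experiment
    drivers for sampling-convergence, particle-tracking and noise sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    deSolve,
    minpack.lm,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
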