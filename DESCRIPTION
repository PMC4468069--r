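Package: MEAflow
Title: Activation Mapping and Conduction Velocity Analysis for Microelectrode Array Recordings
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis of extracellular field potentials recorded on planar
    60-electrode microelectrode arrays (MEAs), with a focus on cardiomyocyte
    monolayers. Provides Savitzky-Golay smoothing of electrode traces,
    activation-time detection at the steepest negative voltage slope
    (dV/dt minimum), least-squares fitting of a quadratic activation-time
    surface T(x, y) and derivation of per-electrode conduction-velocity
    vectors from its spatial gradient (the Bayly method), beat detection and
    beat-rate quantification, seeded electrode-dropout and white-noise
    robustness experiments, a synthetic wavefront simulator with exact ground
    truth, and figure production (trace grids, activation heat maps,
    isochrone maps, velocity vector fields, 3D signal-progression frames).
    Reads and writes the tab-delimited ASCII export format of common MEA
    acquisition tool chains.
License: GPL-3
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    signal,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Electrophysiology, Software, Visualization, Preprocessing
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'MEAflow-package.R'
    'preprocess.R'
    'activation.R'
    'layout.R'
    'io.R'
    'velocity.R'
    'serialize.R'
    'viz.R'
    'pipeline.R'
    'synth.R'
    'robustness.R'
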