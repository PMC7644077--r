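Package: cellmag
Title: Motion Magnification and Spectral Analysis of Periodic Cell Motion in
    Time-Lapse Microscopy
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Detects, spectrally characterizes, magnifies and annotates
    imperceptible periodic motions of biological cells in time-lapse
    microscopy videos. Restricts analysis to cell-edge pixels, estimates the
    motion power spectrum of their intensity series with a Blackman-Tukey
    (autocorrelation) estimator, identifies the dominant oscillation
    frequency, amplifies motion at that frequency with phase-based Eulerian
    video magnification on a complex steerable pyramid, localizes significant
    motion on a pixel grid with per-direction center-of-mass amplitude
    scores, colors expansion/contraction phase on kymographs, and validates
    amplified motion against a static control through a Lucas-Kanade
    optic-flow degree-of-motion curve. Includes a synthetic fixture generator
    (pulsating ring, sub-pixel oscillating texture, drift, static noise)
    with exact ground truth so every stage is testable without microscope
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    tiff,
    EBImage,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
biocViews: CellBiology, Visualization, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'accessors.R'
    'cellmag-package.R'
    'utils.R'
    'edges.R'
    'pyramid.R'
    'evm.R'
    'motion.R'
    'videoio.R'
    'preprocess.R'
    'synthio.R'
    'validate.R'
    'spectrum.R'
    'pipeline.R'
    'plots.R'
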