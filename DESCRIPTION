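Package: uvqdpc
Title: Quantitative Differential Phase Contrast Microscopy in the Deep Ultraviolet
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and reconstruction toolkit for reflection-geometry
    quantitative differential phase contrast (qDPC) microscopy with an
    obscured annular pupil in the UVC band. Models partially coherent
    oblique half-ring illumination through a Cassegrain-type objective,
    simulates intensity image formation from complex-refractive-index
    phantoms (weak-object transfer functions plus a brute-force Abbe
    oracle), jointly retrieves absorption and phase by Tikhonov-regularized
    inversion, converts absorption to quantitative extinction-coefficient
    maps, calibrates illumination direction and pupil shape from images,
    and provides contrast metrics and fenestration-cluster analysis for
    liver sinusoidal endothelial cell imaging.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    graphics,
    EBImage,
    tiff,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
biocViews: Software, Microscopy, ImageProcessing
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'calibration.R'
    'cli.R'
    'fenestration.R'
    'forward.R'
    'fourier-utils.R'
    'instrument-formulas.R'
    'io.R'
    'metrics.R'
    'optics.R'
    'phantom.R'
    'reconstruct.R'
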