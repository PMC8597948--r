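Package: probeloc
Title: Electrode Localization for Linear Probes in Standardized Brain Coordinates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs the anatomical position of every recording site of a
    linear electrophysiology probe (Neuropixels-class) in a standardized brain
    coordinate system. Provides landmark-based 3D thin-plate-spline warping
    between image spaces, arc-length parametrized probe-track reconstruction
    from annotated dye tracks, electrode placement anchored to
    electrophysiological landmarks with piecewise-linear depth scaling, atlas
    region assignment, extracellular preprocessing (offset removal, common
    average referencing, AP/LFP band split, multiunit threshold detection), and
    a groundtruth accuracy analysis that compares fluorescence peaks with
    photostimulation-evoked activity peaks via multi-term Gaussian fits. A
    fully seeded synthetic phantom generator with known ground truth supports
    validation of the complete pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    minpack.lm,
    signal,
    stats,
    tiff,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
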