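Package: fidvol
Title: Simulation and Volumetry of Injectable Liquid Fiducial Markers in CT
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantitative evaluation of low-dose injectable iodinated liquid
    fiducial markers in head-and-neck computed tomography. Provides a digital
    phantom of soft tissue, bone and teeth with superficially injected iodine
    markers and hyperdense confounders; a forward model for single- and
    dual-energy CT acquisition with kV-dependent iodine contrast,
    partial-volume blur and noise; threshold-based 3D connected-component
    segmentation and volumetry of markers; norm-interval descriptive
    statistics and paired tube-voltage comparisons; a discriminability
    statistic deciding whether two injection volumes are reliably
    distinguishable; and two-material dual-energy decomposition (virtual
    non-contrast images and iodine maps) with classification of hyperdense
    objects as iodine markers versus metal clips or calcifications.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
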