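Package: tomosta
Title: Subtomogram Averaging of Membrane-Embedded Particles with
    Missing-Wedge Compensation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale subtomogram-averaging toolkit for cryo-electron
    tomography of large membrane proteins such as the ryanodine receptor in
    native sarcoplasmic-reticulum membranes. Implements missing-wedge
    constrained cross-correlation alignment, cross-correlation- and
    dose-weighted averaging with C4 symmetrization, independent half-set
    refinement with Fourier shell correlation resolution estimation,
    multireference classification with class pruning and occupancy reporting,
    eigenvolume principal component analysis of conformational heterogeneity
    with per-mode half-maps, and membrane-curvature estimation by
    spherical-coordinate flatness optimization. A phantom generator renders
    synthetic C4 receptor/membrane particles with known poses, classes,
    deformation modes and membrane curvature under a dose-symmetric tilt
    scheme, so every stage can be validated against a recoverable ground
    truth. Volumes are read and written in MRC2014 format and particle
    metadata in tab-separated tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
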