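Package: mesoqc
Title: Quality-Control Analytics for Light-Sheet Microscopes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative quality control for light-sheet (and other
    widefield-detection) microscopes from simple calibration acquisitions.
    Computes percentile-based contrast maps of a back-illuminated Ronchi
    ruling over a focus sweep, estimates the best-focus surface, the
    tilt-corrected field-flatness sag, depth of field, maximum-contrast
    uniformity and chromatic focal offsets; measures the point-spread
    function by detecting and Gaussian-fitting sub-resolution beads in 3D
    volumes; and validates sparse fluorescent structures (e.g. radiation
    induced color centers) by normalized cross-correlation against a
    repeated scan with a Gaussian null model. Ground-truthed simulators
    for all three acquisition types support end-to-end verification.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    grDevices,
    graphics,
    jsonlite,
    minpack.lm,
    optparse,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
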