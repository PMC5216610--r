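Package: dxr
Title: Digital X-Ray Radiogrammetry of Metacarpal Cortical Bone
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for digital X-ray radiogrammetry (DXR) of tubular bones:
    a synthetic metacarpal phantom generator with exact ground-truth geometry,
    contour detection with proximal/distal end identification, placement of
    shaft measurement regions by either the proportional (44% of bone length)
    or the narrowest-point rule, sub-pixel localisation of the outer cortical
    border (maximum gradient) and inner border (maximum radio-opacity),
    the metacarpal index (MCI) and bone health index (BHI) family of cortical
    indices, automatic three-way self-validation of measurements, and
    bootstrap statistics for comparing correlated cortical indices against
    clinical severity scores.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    grDevices,
    utils,
    tools,
    jsonlite,
    png,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
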