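Package: skinqa
Title: Image-Quality Evaluation for Stretchable Scintillator X-Ray Detectors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to evaluate the image quality of stretchable scintillator
    X-ray detectors ("imaging skins") imaged by an external scientific camera.
    Implements deformable-region flat-field and dark-field correction, signal
    transfer property (STP) linearity analysis against air kerma, slanted-edge
    spatial frequency response (e-SFR) estimation with SFR50/SFR10 summaries in
    line pairs per millimetre, and stretch-series analysis (elongation
    bookkeeping, volume-conserved thickness estimation, trend fits, and
    Bhattacharyya distances between mean-removed pixel histograms). A seeded
    synthetic frame-stack simulator reproduces the statistical structure of the
    physical rig so that every analysis stage is testable without hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    graphics,
    jsonlite,
    pracma,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2,
    knitr
Config/testthat/edition: 3
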