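Package: kinetoquant
Title: Quantitation of Kinetochore Fluorescence Foci in 3D Image Stacks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for measuring the brightness and size of diffraction-limited
    kinetochore foci in 3D widefield fluorescence z-stacks of budding yeast.
    Implements dual-ROI background-subtracted intensity quantitation (a fixed
    kinetochore box with a surrounding fixed-volume background shell),
    marginal-sum 1D Gaussian morphometry (averaged FWHM and peak height),
    control-normalized population comparison with Welch's t test, and a seeded
    synthetic z-stack generator with known ground truth so every stage of the
    pipeline can be validated against planted effect sizes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tiff,
    minpack.lm,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
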