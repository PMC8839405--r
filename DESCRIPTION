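Package: dermabcd
Title: ABCD Dermoscopic Scoring of Skin Lesion Photographs
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: End-to-end analysis of single-lesion skin photographs by the
    dermoscopic ABCD rule. Provides image preprocessing (median denoising,
    grayscale morphological closing for hair removal, piecewise-linear
    contrast clipping), three-class multilevel Otsu segmentation of the
    lesion, the four ABCD criterion scores (reflection non-overlap and
    chi-square colour-histogram asymmetry, eight-sector border
    irregularity, six-colour reference-palette distances, and millimetre
    diameter under a fixed optical calibration), the combined total
    dermatoscopic value (TDV) with a three-way diagnostic label, and a
    seeded synthetic-lesion generator with analytic ground truth for
    testing every pipeline stage without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    jpeg,
    png,
    tiff,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
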