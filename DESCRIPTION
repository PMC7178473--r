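Package: dermofill
Title: Filled-Function Global Optimization and Otsu Thresholding for
    Dermoscopic Lesion Segmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A smoothed filled-function (auxiliary-function) method for
    nonsmooth global optimization on box domains, built from an elimination
    function, a monotone Bernstein-curve smoothing bridge, and a rational
    escape term; a random-direction one-dimensional reduction search driven
    by it; and a dermoscopic image segmentation pipeline that uses the
    optimizer to locate the Otsu within-class-variance threshold on the red
    channel after median and Gaussian smoothing.  Includes mask
    post-processing (field-of-view corner masking, largest connected
    component, border-failure detection), overlap metrics (accuracy,
    Jaccard, Dice, sensitivity, specificity, predictive values), seeded
    synthetic dermoscopy-like image and histogram generators with ground
    truth, and a command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    tools,
    utils
Suggests:
    tiff,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
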