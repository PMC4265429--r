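Package: retfractal
Title: Grayscale Fractal Dimension of the Retinal Vasculature from
    Optic-Disc-Centred Fundus Images
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Unsupervised measurement of retinal vascular complexity from
    optic-disc-centred fundus photographs using the differential
    (grayscale) box-counting fractal dimension. The pipeline detects the
    optic disc with an active-contour model, crops a square region of
    interest spanning four disc diameters, enhances vessel contrast on
    the inverted green channel with a bank of oriented Gabor filters,
    and estimates the fractal dimension from the log-log slope of
    per-scale box counts. Includes a binary box-counting comparator,
    seeded synthetic generators (fractional Brownian surfaces with known
    theoretical dimension, fundus-like images with ground-truth disc and
    vessel masks, and cohort tables with configurable covariate and
    fractal-dimension structure), and the cohort statistical layer
    (normality testing, one-way and two-factor ANOVA with pooled-variance
    confidence intervals, and multivariate ordinary least squares).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    png,
    nortest,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    tiff
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
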