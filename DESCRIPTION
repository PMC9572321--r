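Package: ripegrade
Title: Machine-Vision Ripeness Grading of Fruit Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An image-processing pipeline for grading single-fruit images
    into four ripeness stages. Segments a fruit from a near-white background
    by thresholding and binary morphology, decomposes the masked image into
    19 scalar channels across six colour spaces (RGB, CIELAB, Ohta I1I2I3,
    normalized rgb, chromatic CrCgCb, HSV) plus gray, extracts 15 first-order
    and gray-level co-occurrence texture statistics per channel (285 features
    per image), selects features by forward sequential selection under a
    cross-validated quadratic-discriminant criterion, and classifies with
    linear/quadratic discriminant analysis and a single-hidden-layer neural
    network with tanh units. Includes a synthetic labelled-image generator
    that emulates the four-stage study design for end-to-end testing, and
    evaluation via confusion matrices, correct classification rate, mean
    squared error and correlation coefficients.
License: MIT
Encoding: UTF-8
Imports:
    EBImage,
    grDevices,
    jsonlite,
    png,
    stats,
    utils
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
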