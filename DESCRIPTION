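Package: fluoragg
Title: Fluorescence Microscopy Image Analysis for Therapeutic Protein
    Aggregates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects and sizes sub-visible therapeutic-antibody aggregates
    in fluorescence microscope images. Provides a denoising chain (median
    filtering, total-variation gradient descent, FFT low-pass background
    normalization), four thresholding methods (weighted median, 1D Otsu,
    2D Otsu on the joint grayscale/average-grayscale histogram, and a
    modified 2D Otsu that iteratively tunes the average-grayscale
    threshold against a particle-count estimate), binary morphology
    cleanup, and per-particle morphometrics (area, perimeter,
    circularity, equivalent radius) with 10-micrometre size-distribution
    binning. Includes a seeded synthetic-scene generator emulating
    FITC-tagged aggregate images for validation, a batch pipeline, and
    broom-style tidiers plus ggplot2 autoplot methods for all result
    types.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
Suggests:
    EBImage,
    jpeg,
    knitr,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
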