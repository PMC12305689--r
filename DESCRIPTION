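Package: gfaptile
Title: Tile-Based Quantification of Reactive Astrocyte Response to Focal
    Proton Irradiation in Brain Slices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies the spatial distribution and dose dependence of
    reactive astrocytes (GFAP immunofluorescence) in brain slice images
    after partial-brain proton irradiation. Implements the full analysis
    chain: rolling-ball background subtraction, 8-bit conversion, Otsu
    thresholding and area filtering of GFAP-positive segments; tile-based
    area-fraction maps; affine co-registration and resampling of a
    simulated dose grid into slice coordinates; mirrored hemisphere
    regions of interest; depth and transverse dose/GFAP profiles; and a
    linear dose-response fit with a Wald test. A synthetic phantom module
    generates two-channel slice images with matched dose fields and
    ground-truth masks so that every stage is testable without animal
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    graphics,
    grDevices,
    tools,
    utils,
    tiff
LinkingTo:
    Rcpp
Suggests:
    EBImage,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
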