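Package: angiopath
Title: Two-Stage Morphometric Segmentation of Vessels in IHC Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Segmentation and morphometry of blood and lymphatic vessels in
    brightfield immunohistochemistry images (DAB-stained tissue-microarray
    cores). A colour stage isolates closed brown-stained vessels by HSV
    thresholding, morphological cleanup and contour tracing with hole
    hierarchy; a radial stage detects bright vascular lumens, probes outward
    along boundary normals for membrane staining, and closes open vessels.
    Per-vessel shape measures (area, size, aspect, roundness, perimeter
    ratio) and image-level vascular density are reported in pixels and
    calibrated micrometres. Includes a synthetic scene generator with
    object-level ground truth and a sensitivity/specificity scorer, plus a
    command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    tiff,
    png,
    jpeg,
    yaml,
    stats,
    utils,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    EBImage
Config/testthat/edition: 3
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
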