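Package: cytospinr
Title: Automated Cytospin Image Analysis for Schwann Cell Purity and
    Proliferation
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Quantifies cell-culture purity and proliferation from
    four-channel immunofluorescence images of cytospun cells (DAPI, SOX10,
    EdU, vimentin).  Implements global Otsu thresholding, shape-based
    declumping of touching nuclei, circularity filtering of burst nuclei,
    per-object marker-intensity classification, seeded propagation
    segmentation of cell bodies with an intensity/distance regularization
    trade-off, nested counting of real cells, Schwann cells and
    proliferating Schwann cells, overlay rendering, spreadsheet export,
    and a paired comparison against manual counts.  A synthetic cytospin
    generator with exact ground truth supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    png,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tiff,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
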