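Package: tpmquant
Title: Ratiometric Quantification of Tropomyosin Decoration on Actin Structures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-channel fluorescence microscopy pipeline for measuring how
    strongly tropomyosin decorates each class of F-actin structure (endocytic
    patches, interphase cables, the cytokinetic ring) in rod-shaped yeast
    cells, relative to an F-actin reporter. Provides calibrated TIFF stack
    I/O, z-projection, photobleaching correction, two-channel translation
    registration, trainable per-pixel segmentation of cytoskeletal structures,
    per-cell instance detection with clump rejection, percentile-trimmed ROI
    intensity statistics, the normalized decoration-ratio statistic with
    per-class aggregation, kymograph construction along the cell long axis,
    and a ground-truthed synthetic scene generator (Gaussian PSF, Poisson and
    read noise) for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    ranger,
    jsonlite,
    yaml,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
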