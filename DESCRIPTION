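Package: carpelseg
Title: Machine-Learning Phenotyping of Stigma and Ovary Development in Wheat Carpels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies late development and senescence of unpollinated wheat
    carpels from RGB stereo-microscopy images. A small encoder-decoder
    convolutional network (trained with a soft-Dice loss and Adam updates)
    segments the stigma-hair envelope and the ovary; masks are converted to
    stigma area (mm^2, pixel counting) and ovary diameter (mm, centroid-
    perpendicular chord). Agreement between annotation sources is scored with
    the Dice similarity coefficient. Per-carpel time courses are filtered by
    the interquartile-range criterion, smoothed with Loess, normalised by
    cumulative degree days, and classified into growth, peak and deterioration
    phases used to rank male-sterile cultivars. A seeded synthetic-data module
    generates carpel images with ground-truth masks, measurement trajectories
    with known phase boundaries, and temperature series, so the whole pipeline
    is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
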