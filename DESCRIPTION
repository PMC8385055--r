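Package: dropcyto
Title: Droplet Microfluidics Single-Cell Cytotoxicity Image Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated analysis of time-lapse fluorescence microscopy of
    cell pairs co-encapsulated in picolitre water-in-oil droplets, as used
    in single natural-killer-cell cytotoxicity assays. Detects immobilised
    droplets in brightfield images with a circular Hough transform, links
    them across hourly timepoints while removing moving droplets, counts
    effector and target cells per droplet from tracker-dye channels,
    calls per-cell death times from a viability-dye channel, and derives
    killing-kinetics statistics (killer fraction, fast/slow killer split,
    serial killers). Includes a two-species Poisson co-encapsulation model
    and a ground-truthed synthetic time-lapse image generator so every
    pipeline stage can be validated without experimental images.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    EBImage,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
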