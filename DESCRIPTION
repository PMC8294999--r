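Package: hotspotseg
Title: Detection and Segmentation of Metastatic Hot Spots in Spinal MRI Slices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A cascade for detecting and segmenting bright metastatic "hot
    spots" in 2-D spinal MRI slices: unsupervised patch-based sparse-coding
    features, an AdaBoost triage classifier with a three-level
    (certain/uncertain/negative) decision band, a MILBoost multi-instance
    hot-spot scanner producing a per-pixel probability map, and a Chan-Vese
    region-based level-set segmenter initialized from the binarized map.
    Includes Otsu-threshold and seeded region-growing baseline segmenters,
    Dice/Jaccard evaluation, and a synthetic spine-phantom generator with
    ground-truth masks standing in for clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    jsonlite,
    yaml,
    png,
    generics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
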