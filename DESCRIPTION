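Package: zebrascore
Title: Detection and Area-Fraction Scoring of Foamy Podocytes in Renal Histology
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A computational-pathology pipeline for screening renal biopsies for
    Fabry nephropathy from routine H&E/PAS histology. Extracts
    resolution-normalized glomerular tiles, trains small convolutional
    classifiers and segmenters for foamy (vacuolated) podocytes with
    case-level cross-validation, computes the ZEBRA score (foamy-podocyte
    area as a percentage of glomerular area) per glomerulus and per case,
    and evaluates results with bootstrap confidence intervals, ROC/Youden
    cutoff selection, Spearman correlation and Mann-Whitney tests. Includes
    a synthetic glomerulus generator with ground-truth masks so the whole
    pipeline is testable without whole-slide images, and QuPath-dialect
    GeoJSON annotation interchange.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    grDevices,
    jsonlite,
    png,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
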