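Package: imctme
Title: Spatial Single-Cell Analysis of Multiplexed Imaging Mass Cytometry Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end, reproducible pipeline for spatial single-cell
    analysis of imaging mass cytometry (IMC) tissue cores. Implements
    marker-mask-based cell phenotyping (median smoothing, intensity-level
    quantization, foreground selection, blob removal, adaptive refinement,
    and per-cell majority voting over lineage marker masks), permutation
    tests for pairwise cell-cell interaction and avoidance, cellular
    neighbourhood discovery by clustering nearest-neighbour composition
    windows, z-score stratified Kaplan-Meier and log-rank survival
    association, and an image-embedding / sparse-PCA / RBF-SVM framework
    for predicting clinical outcomes from multichannel images. Ships a
    synthetic cohort generator (marked point process with planted niches,
    pairwise attraction or avoidance, and outcome models) so every stage
    can be exercised and validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Matrix,
    data.table,
    tiff,
    survival,
    e1071,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
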