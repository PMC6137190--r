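Package: fishcam
Title: Automated Fish Abundance Estimation from Fixed Underwater Camera Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Content-based recognition pipeline for counting fish in
    time-stamped image sequences from fixed underwater cameras (cabled
    observatories). Consecutive-frame differencing suppresses static
    background and bio-fouling; candidate regions of interest are
    characterised by the convex hull of difference blobs and described by
    texture and shape features; a genetic-programming binary classifier
    trained inside a repeated, class-balanced, stratified 10-fold
    cross-validation turns regions into per-image fish counts. Includes
    abundance time-series aggregation at 30-minute, day/night and monthly
    scales, stratified Pearson correlation against manual counts,
    univariate permutation PERMANOVA with pairwise contrasts, an
    autocorrelation pre-filter for covariates, and a fully ground-truthed
    synthetic underwater scene generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    Rcpp,
    grDevices,
    jsonlite,
    png,
    stats,
    tools,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jpeg,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
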