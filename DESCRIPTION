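Package: subprep
Title: Preprocessing of Subcellular Two-Photon Calcium Imaging Traces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Preprocessing pipeline for fluorescence traces extracted from
    subcellular regions of interest (axons, dendrites) in two-photon calcium
    imaging. Selects ROIs that contain real calcium transients by their
    normalized spectral power in a transient frequency band, detects and
    removes synchronous z-plane movement artifacts with principal component
    analysis and bottom-up change-point segmentation, extracts significant
    transients after rolling-percentile baseline correction to dF/F, and
    groups ROIs belonging to the same neuron by correlation clustering with
    silhouette and adjusted-mutual-information model selection. Includes a
    synthetic session generator with planted ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    cluster,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
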