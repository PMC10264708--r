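Package: rhizotrack
Title: Root System Architecture Traits from Time-Lapse Rhizobox Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Semi-automated phenotyping of seedling root systems grown in
    glass-fronted rhizoboxes and imaged by a fixed camera. Frame sequences
    are binarized, cleaned, reduced to one-pixel topology-preserving
    skeletons and converted to graphs of endpoints and junctions joined by
    pixel chains with geodesic lengths. From mask, graph and a grain
    landmark the package computes per-frame root-system-architecture
    traits (total and longest root length, primary root angle, convex hull
    area, bounding-box width, root area, root growth angle and seminal
    root growth angle), assembles them into timestamped series with
    emergence detection, and ships a parametric root-system simulator with
    analytic ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    png,
    tiff,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
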