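Package: vinerows
Title: Row Segmentation, Trunk Detection and Canopy Parameters from
    Vineyard Point Clouds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Processes georeferenced 3D point clouds of vineyards acquired
    from unmanned aerial vehicles (photogrammetric or LiDAR). Separates
    ground from vegetation with a cloth-simulation filter, height-normalizes
    the plant cloud against a terrain model, segments individual vine rows
    by density-based clustering with orientation-aware centroid merging,
    detects single trunk positions from local covariance sphericity with
    Otsu auto-thresholding, and extracts per-segment canopy height, width,
    alpha-shape volume and lower bound along each row. Includes a synthetic
    vineyard generator with full ground truth and evaluation metrics for
    row segmentation accuracy and radius-based trunk matching.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    data.table,
    jsonlite,
    yaml,
    tibble,
    ggplot2,
    stats,
    utils,
    tools,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
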