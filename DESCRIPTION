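Package: caspzone
Title: Management Zone Delineation by Clustering and Smoothing of
    High-Resolution Soil Sensor Data
Version: 1.0.0
Authors@R:
    person("Sam", "Verhoeven", email = "sam.verhoeven@posteo.net",
           role = c("aut", "cre"))
Description: Delineates agricultural management zones from proximal and
    remote soil-and-crop sensing data. Provides ordinary kriging of
    irregular point samples onto a common regular grid after
    semivariogram fitting, range normalization, correlation-based
    feature selection, five clustering algorithms (k-means, fuzzy
    C-means, mean shift, agglomerative hierarchical, DBSCAN), cluster
    validity scoring (Davies-Bouldin index, Silhouette index, variance
    reduction index), and density-based smoothing that removes small
    cluster islands so zone maps can be actuated by variable-rate
    machinery. A synthetic field simulator with known zone structure,
    spatially autocorrelated cross-correlated attributes, and transect
    sampling supports end-to-end testing without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
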