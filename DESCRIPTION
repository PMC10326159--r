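Package: gwtau
Title: Scalable Gromov-Wasserstein-Type Distances for Biological Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compares multivariate time series (trajectories) of possibly
    different dimensions and lengths through the distribution of their
    cumulative arc-length distances from the start. The resulting
    Gromov-Wasserstein-type distance has a closed-form expression as a
    one-dimensional Wasserstein distance between distance-from-start
    profiles, making it linear-time for equal-length series. Ships the
    Third Lower Bound (TLB) and an exact linear-programming transport
    oracle for validation, Euclidean and dynamic time warping baselines,
    a distance-based analysis workflow (1-nearest-neighbour
    classification, k-medoids and hierarchical clustering,
    multidimensional-scaling embedding with k-means, trajectory
    averaging assessment), seeded synthetic trajectory generators, and
    readers and writers for long-format and flat time-series tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    boot,
    cluster,
    deSolve,
    dplyr,
    generics,
    ggplot2,
    mclust,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
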