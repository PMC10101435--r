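Package: netspectra
Title: Spectral-Density Clustering of Whole Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for grouping whole graphs by connectivity structure.
    Each graph is summarised by the smoothed density of its adjacency
    eigenvalues; densities are compared with Kullback-Leibler and
    Jensen-Shannon divergences. Two clustering algorithms are provided: a
    k-means in square-root Jensen-Shannon distance for collections of
    same-size graphs, and gCEM, a model-based expectation-maximisation
    scheme that clusters graphs of different sizes by fitting random-graph
    model parameters with a KL-minimising Monte-Carlo estimator. Includes
    five random-graph generators, degree-preserving edge rewiring, a
    pair-counting Jaccard index, simulation-scenario runners, and a
    pipeline that builds thresholded correlation networks from
    multichannel signals and detects state transitions in the clustered
    network sequence.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    Matrix,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    pracma,
    readr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
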