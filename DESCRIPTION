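Package: contourgate
Title: Density-Contour Clustering for Automated Flow-Cytometry Gating
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Unsupervised density-contour clustering of large multidimensional
    event tables such as flow-cytometry measurements. Builds a histogram with
    a Bayesian optimal bin number, sweeps its level sets from the top down,
    labels bin aggregates with a percolation-style connected-component
    routine, separates statistically significant peaks from Poisson counting
    fluctuations, and reports each population as the largest still-separated
    histogram cross section ("tight" gating that leaves low-density events
    unassigned). Includes a principal-component pathway for data above five
    dimensions, a distorted-Gaussian benchmark simulator, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils
Suggests:
    igraph,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
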