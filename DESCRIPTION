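Package: cimnet
Title: Cybernetic-Inspired Modeling of Stage-Specific Transcriptional
    Regulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Infers a preliminary causal gene-gene network from longitudinal
    expression data using time-delayed mutual information computed on
    AR/VAR innovations (the innovation approach, with kernel density
    estimates of the innovation distributions), fits a stage-specific
    cybernetic ordinary differential equation model of transcriptional
    regulation to the time series by multistart bounded least squares with
    sparsity projection, and reduces the fitted interaction network with
    maximal clique centrality and maximal RNA expression rate criteria.
    Includes a synthetic-data generator with planted causal structure for
    benchmarking direction, lag, and parameter recovery, plus SIF/GraphML
    network export and a command-line pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    igraph,
    minpack.lm,
    pracma,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
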