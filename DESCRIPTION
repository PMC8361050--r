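Package: grntda
Title: Persistent Homology and Structural Balance of Gene Regulatory Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers signed weighted gene regulatory networks from expression
    data with a maximum-entropy Gaussian model whose couplings are estimated
    by a sparse penalized maximum-likelihood (graphical lasso) precision
    matrix, characterizes the resulting signed networks with structural
    balance theory (triad census, energy landscape, quartic balance energy),
    and compares cohorts through persistent homology of weighted clique
    complexes: Z2 boundary-matrix reduction, persistence diagrams and
    barcodes, Betti curves and essential classes. Includes a synthetic-data
    module generating multivariate Gaussian expression cohorts with known
    sparse signed precision matrices and toy weighted networks with known
    homology, so that every stage is testable against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    igraph,
    MASS,
    jsonlite,
    Rcpp,
    SummarizedExperiment
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
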