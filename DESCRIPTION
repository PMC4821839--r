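Package: pathrider
Title: Pathway- and Network-Guided Sparse Regression for Imaging Genetics
Version: 0.1.0
Authors@R:
    person("pathrider", "developers", email = "pathrider@example.org",
           role = c("aut", "cre"))
Description: End-to-end analysis of multivariate quantitative traits against
    genome-wide genotypes using biological grouping priors. Provides genotype
    quality control and SNP-to-gene-to-pathway grouping, covariate
    residualization and scree-elbow PCA reduction of the phenotype,
    identity-by-state population stratification diagnostics, pathway-level
    sparse reduced-rank regression with overlapping group penalties, adaptive
    pathway-weight tuning against null selection bias and stability-selection
    ranking, a graph-guided group lasso over the genes of a single pathway
    with a GO-similarity network prior, hypergeometric over-representation
    tests, and a synthetic-data generator with planted ground truth for
    validating recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    data.table,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
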