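Package: popstrat
Title: Stratification Analysis of Closely Related Livestock Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying the degree of stratification between two
    closely related livestock populations genotyped on a common SNP panel.
    Implements per-population marker quality control and marker-set
    intersection, pairwise linkage-disequilibrium (r2) estimation with
    distance binning and decay regression, SNP-BLUP estimation of random
    marker effects from deregressed breeding values via Gauss-Seidel
    iteration with residual update, gene-content BLUP estimation of
    base-population allele frequencies from pedigree, window-based testing
    of regional additive-variance differences with false-discovery-rate
    control, and EM-REML estimation of the cross-population SNP-effect
    (co)variance matrix and genetic correlation. A synthetic-data generator
    produces two-population datasets with drift from a common base,
    population-specific distance-dependent linkage disequilibrium,
    cross-population correlated SNP effects, and deregressed proofs weighted
    by effective daughter contributions, so the whole pipeline is testable
    without proprietary evaluation data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    Matrix,
    methods,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
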