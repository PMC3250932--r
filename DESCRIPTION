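Package: kinfold
Title: Genomic Prediction with Relationship-Aware Cross-Validation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for genomic prediction in pedigreed, SNP-genotyped
    livestock populations: deregression of estimated breeding values with
    reliability-derived weights, a weighted BayesC Gibbs sampler for marker
    effect estimation, pedigree numerator relationship matrices and
    pedigree-dissimilarity K-means clustering for relationship-aware
    cross-validation folds, pooled validation statistics (accuracy, bias,
    parent-average blending), and a weighted bivariate animal-model REML
    for the genetic correlation between a trait and its direct genomic
    value. Includes a seeded population simulator (multi-generation
    pedigrees with patrilineal half-sib families and a closed inbred line,
    LD-bearing genotypes, and EBV records of configurable reliability) so
    the full analysis runs without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
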