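Package: hetvar
Title: GWAS of Genetic Heterogeneity of Residual Variance in Sire Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study the genetic control of trait uniformity
    (micro-environmental sensitivity) in large half-sib families. Fits a
    bivariate sire double hierarchical generalized linear model (DHGLM) for
    the mean and the log residual variance of a quantitative trait, builds
    deregressed-EBV and log-residual-variance response variables for
    association studies, runs a BayesC mixture-prior Gibbs sampler with
    heterogeneous residual weights, and summarises results as Bayes factors,
    non-overlapping 1-Mb window variance shares, top-window overlaps and
    scale-effect tests. Includes a synthetic-data generator that emulates a
    progeny-tested beef cattle design (large half-sib families, contemporary
    groups, age-by-sex covariates, SNP and polygenic effects on both the
    mean and the log residual variance) so the whole pipeline can be
    exercised and validated without proprietary data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
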