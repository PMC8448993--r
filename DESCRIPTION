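Package: quantherit
Title: Quantile-Specific Heritability from Family Phenotype Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates narrow-sense heritability of a quantitative trait as a
    function of its distribution quantiles, from pedigree phenotype data.
    Implements sex/age adjustment of repeated exam measurements within
    cohorts, construction of weighted offspring-parent and full-sib pair
    sets, an exact weighted simple quantile-regression solver with joint
    bootstrap covariance across a percentile grid, transformation of
    regression slopes to heritability under phenotypic assortative mating,
    and orthogonal-polynomial trend tests for quantile dependence.  Includes
    a synthetic multi-cohort pedigree generator with additive genetic
    effects, assortative mating, and an optional monotone transform that
    induces quantile-dependent effect sizes, so the whole pipeline can be
    validated by simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
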