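Package: sibige
Title: Estimating Indirect Genetic Effects of Siblings from Singleton
    and Non-Singleton Polygenic Score Associations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for evaluating indirect genetic effects (IGEs) of
    siblings by comparing polygenic score (PGS) associations between
    individuals without full siblings (singletons) and individuals with
    siblings (non-singletons).  Provides a family-structured PGS and
    phenotype simulator under random and assortative mating, a synthetic
    biobank-style cohort generator with sibship-size, birth-order,
    adoption and missingness structure, greedy LD clumping and PGS
    scoring from GWAS summary statistics, the estimator algebra
    (covariate-adjusted stratified OLS, delta-method differences and
    percent attenuation, sibling-count interaction models, and the
    times-two scaling of the difference to a per-sibling IGE), and an
    end-to-end replication pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
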