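Package: adipoplane
Title: Joint-View Classification of Adiposity GWAS Signals on the BMI-WHR Effect Plane
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Downstream analysis of genome-wide association summary statistics
    for correlated adiposity traits (body mass index, waist-to-hip ratio, and
    WHR adjusted for BMI). Reads and harmonizes GIANT-style summary-statistics
    tables, selects and clumps genome-wide significant signals across the three
    scans, converts between covariate-adjusted and unadjusted genetic effects
    with propagated uncertainty, classifies lead variants into four classes on
    the b_WHR vs b_BMI effect plane, runs class-specific directional binomial
    enrichment tests and class-restricted inverse-variance-weighted Mendelian
    randomization, and ships a seeded synthetic-cohort generator so that every
    stage is testable without external consortium data.
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
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
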