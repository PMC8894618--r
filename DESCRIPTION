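Package: degconcord
Title: Sign Concordance of Domestic-Versus-Wild Expression Divergence with
    Human Reproductive-Potential Gene Annotations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers per-lineage expression-divergence polarity of
    domestic/wild animal differentially expressed gene (DEG) pairs relative
    to their most recent common ancestor, matches the animal genes to human
    orthologs curated for the effect of under- and overexpression on
    reproductive potential, tallies codirected correspondences into a 2x2
    lineage-by-effect contingency table, and evaluates it with a two-sided
    Fisher exact test, Pearson chi-square tests (with and without Yates
    correction) and exact one-sided binomial tests, all implemented from
    first principles. Ships a worked-example fixture bundle, a synthetic-data
    generator with ground truth, and a Monte-Carlo type-I-error calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
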