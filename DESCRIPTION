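Package: metapqtl
Title: Metaprotein Factor Models and pQTL Association for LC-MS Peptide Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Aggregates label-free LC-MS peptide (isotope-group) quantitation
    into protein-level "metaprotein" expression scores with a sparse
    spike-and-slab one-factor model fitted per seed protein, scans the scores
    for association with a biallelic SNP genotype under additive and recessive
    codings with covariate adjustment and Bonferroni control, tests component
    peptides individually, and assesses mediation of a binary treatment
    outcome with nested logistic regressions (profile-likelihood intervals,
    likelihood-ratio tests, and a bias-reduced fallback under separation).
    Includes a synthetic-cohort generator with Hardy-Weinberg genotypes and
    known ground truth, readers and writers for the tabular interchange
    formats, and a reader for MATLAB v5 workspace files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
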