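Package: rvcurse
Title: Winner's Curse and Effect Heterogeneity in Rare-Variant Association Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation study framework for quantifying the competing upward
    (winner's curse / selective inference) and downward (effect heterogeneity)
    biases in effect-size estimation after gene-based rare-variant association
    testing. Implements the score-based linear (CAST) and quadratic (C-Alpha)
    gene-level tests, CMC indicator collapsing with a Wald test, estimation of
    the average genetic effect of a pooled variant set, and two bias-correction
    procedures: out-of-bag bootstrap resampling and the truncated-normal
    conditional-likelihood correction with acceptance-region confidence
    intervals. Includes a synthetic cohort generator emulating a small exome
    gene (n = 321 subjects, 11 rare variants) and a study runner producing
    power, conditional-moment and per-variant bias tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2
Config/testthat/edition: 3
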