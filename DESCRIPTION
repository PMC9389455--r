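Package: mimicirt
Title: MIMIC Latent-Regression IRT Models for Brain-Behavior Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits multiple-indicator multiple-cause (MIMIC) models for binary
    item-response data by full-information marginal maximum likelihood: a
    latent trait measured by two-parameter probit/logit items is regressed on
    observed causes (e.g. event-related-potential features), with
    cluster-robust (sandwich) standard errors for repeated-measures designs.
    Includes brute-force uniform and nonuniform differential item functioning
    (DIF) scans with itemset purification, expected a posteriori scoring, a
    population simulator for MIMIC-structured itemsets, and a Monte-Carlo
    parameter-bias study comparing sum-score, two-stage IRT and joint MIMIC
    summaries of behavior via a factorial ANOVA with eta-squared and Cohen's f
    effect sizes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
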