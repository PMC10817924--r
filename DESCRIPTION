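Package: crcdiet
Title: Dietary Patterns, Plasma Metabolite Profiles and Colorectal Cancer
    Risk in Matched Case-Control Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for linking food-frequency-questionnaire dietary patterns,
    untargeted LC-MS plasma metabolite profiles, and colorectal cancer risk in
    individually matched case-control pairs. Derives data-driven dietary
    patterns by a repeated random half-split exploratory/confirmatory
    factor-analysis stability procedure (maximum-likelihood factorization with
    oblimin rotation, Tucker-congruence factor matching), builds
    hypothesis-driven dietary components and energy-density-adjusted
    exposures, estimates per-standard-deviation odds ratios by conditional
    logistic regression with sex and tumor-site stratification, prepares
    metabolite feature matrices (random-forest imputation, quality-control
    coefficient-of-variation filtering), associates diet with the metabolome
    through repeated double cross-validated random-forest variable selection
    with permutation testing of predictive performance (Q2) and
    partial-Spearman validation, and integrates selected features, exposures
    and risk in a principal-component triplot. A seeded synthetic-cohort
    generator with planted factor, metabolome and risk structure provides
    ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    ranger,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
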