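Package: checkupnet
Title: Correlation Network and Longitudinal Analysis of Health-Checkup Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Unbiased association screening of mixed clinical and lifestyle
    questionnaire data from periodic health checkups. Quantifies ordinal
    questionnaire exposures (weekly alcohol grams from volume and frequency
    answer bands), screens all variable pairs by Pearson correlation and the
    correlation ratio, isolates independent associations with the PCIT
    (partial correlation and information theory) trio-tolerance algorithm,
    exports ranked correlation networks in DOT format, and tests longitudinal
    change-change associations between two timepoints with a compound
    significance rule. Includes a seeded synthetic cohort generator with
    planted direct effects, confounders and dose-dependent decline
    attenuation for validating the pipeline against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
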