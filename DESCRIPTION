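Package: lynchscreen
Title: Universal Lynch Syndrome Screening for Endometrial Cancer Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tumor-based triage of endometrial cancer patients for suspected
    Lynch syndrome: microsatellite-instability calling from a five-marker
    mononucleotide panel, mismatch-repair immunohistochemistry loss patterns,
    MLH1 promoter methylation calls from MS-MLPA probe ratios, and a
    rule-based decision tree that assigns sporadic versus suspected-Lynch
    labels with ordered, conditional germline gene-testing plans. Cohort-level
    tools summarise the screening cascade (deficiency, methylation triage,
    genetic-testing attrition, confirmed carriers), estimate observed and
    attrition-corrected mutation prevalence, and compute the usual 2x2
    association statistics (Woolf and exact odds-ratio confidence intervals,
    Pearson chi-squared, pooled t-test from summary statistics). Includes a
    deterministic reference cohort reproducing the published screening
    margins and a seeded stochastic cohort simulator for property and
    recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
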