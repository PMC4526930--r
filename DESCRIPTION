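Package: edtriage
Title: Knowledge-Graph Triage Severity Scoring and Ordinal Agreement
    Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A five-level emergency-department triage severity engine built
    on a curated diagnosis-finding knowledge graph, together with the
    evaluation harness needed to validate any triage scorer against a
    five-level reference standard such as the Emergency Severity Index.
    Diagnoses are ranked for a structured patient presentation by baseline
    prevalence combined with per-finding likelihoods, the top-ranked
    differential is aggregated into a fractional severity, and a mid-band
    rounding rule (driven by critical-test recommendations and symptom
    duration) converts it to an integer acuity of 1 (most severe) to 5.
    The evaluation side provides 5x5 confusion matrices, linearly and
    quadratically weighted Cohen's kappa with bootstrap confidence
    intervals, subgroup analysis, and conventional agreement bands.
    Synthetic knowledge bases and case vignettes with the statistical
    structure the engine assumes can be simulated for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
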