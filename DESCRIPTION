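Package: adhesionrisk
Title: Adhesion Risk Scoring for Gynaecological Surgery
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computes the consensus Adhesion Risk Score (ARS) used to
    stratify women undergoing gynaecological surgery by their risk of
    post-surgical adhesion formation. Implements the two weighted additive
    sub-scores -- the Preoperative Adhesion Risk Score (0-36, ten factors
    from patient history and preoperative findings) and the Perioperative
    Adhesion Risk Score (3-31, ten intraoperative factors) -- together with
    low/medium/high risk stratification, per-factor point breakdowns,
    validated batch scoring of patient cohorts from delimited or structured
    record files, a seeded synthetic-cohort generator with configurable
    factor prevalences, exhaustive profile enumeration for verification,
    and cohort-level risk-distribution reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
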