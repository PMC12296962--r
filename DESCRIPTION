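Package: claimstte
Title: Target Trial Emulation for Claims-Based Anticoagulant Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for emulating a two-arm new-user target trial from
    longitudinal claims-like data: eligibility filtering with attrition
    reporting, grace-period treatment-arm assignment, discrete-time
    person-month expansion with per-protocol artificial censoring,
    stabilized inverse-probability-of-treatment and -censoring weights
    with percentile truncation, and weighted pooled logistic regression
    with cluster-robust variance for intention-to-treat and per-protocol
    hazard ratios, standardized risk curves, and risk differences.
    Includes CHA2DS2-VASc and HAS-BLED score calculators, multiple
    imputation by chained equations, and a synthetic claims-cohort
    generator with known ground-truth effects for validating every
    pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    splines,
    data.table,
    sandwich,
    yaml
Suggests:
    testthat (>= 3.0.0),
    survival,
    jsonlite,
    nnet
Config/testthat/edition: 3
RoxygenNote: 7.3.3
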