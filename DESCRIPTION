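Package: deprescribr
Title: Classify Deprescribing of Type 2 Diabetes Medications in Longitudinal Prescription Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A rules engine that classifies per-patient medication-change
    trajectories in longitudinal primary-care prescription records as
    deprescribing (eight subtypes), not-deprescribing (lateral change,
    medication increase, no change) or unclear, for type 2 diabetes
    pharmacotherapy. Medications are normalized against an editable
    brand/generic/abbreviation lexicon and grouped into three intensity
    tiers (insulin, metformin, other non-insulin agents); prescriptions
    are standardized to daily doses (dose per administration times
    administrations per day); baseline and final 12-month regimen
    snapshots are compared under explicit, auditable rules, including
    inference of discontinuation from an annual-refill policy. A seeded
    synthetic cohort generator plants ground-truth trajectory labels so
    the whole pipeline is testable without any patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
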