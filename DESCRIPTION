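Package: hipcrosswalk
Title: Multi-Directional Crosswalks Between Hip Patient-Reported Outcome Scores
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Scoring engines for the modified Harris Hip Score (mHHS), the
    Hip disability and Osteoarthritis Outcome Score (HOOS) and its 12-item
    short form, together with observed-score equating to build
    multi-directional crosswalks between them.  Implements equipercentile
    equating with mid-percentile ranks and linear continuization, linear
    (ordinary least squares) equating, crosswalk validation by mean absolute
    error overall, per follow-up time point and per pain/activity
    subcategory, a Spearman correlation gate, correlation power analysis via
    the bias-corrected Fisher-z approximation, and a synthetic total hip
    arthroplasty recovery cohort generator for testing the whole pipeline
    without patient data.
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
    withr
Config/testthat/edition: 3
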