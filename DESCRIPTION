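Package: trackfeat
Title: Track Definition and Track Aggregation for Feature Extraction from
    Clinical Event Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Standardized feature extraction for retrospective observational
    studies on OMOP-style clinical event data. Raw event tables (visits, drug
    exposures, measurements, procedures) are first reduced to time-dependent
    per-unit "tracks" -- half-open valued intervals or piecewise-constant
    signals -- via selection, concept mapping, window construction,
    last-observation-carried-forward resampling, thresholding and interval
    algebra; tracks are then aggregated over a period of interest into
    time-independent "features" with a closed catalogue of extraction methods
    (min, max, time-weighted mean, median, durations, counts, delays).
    Tracks and features persist in flat-file TRACK and FEATURE tables that
    follow OMOP naming conventions, with validation and lossless round-trip.
    Includes a seeded synthetic-data generator with planted ground truth and
    reference pipelines for eight study cases (intraoperative hypotension,
    hyperoxemia, drug-drug interactions, potentially inappropriate
    medications, and others).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    readr,
    jsonlite,
    rlang,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
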