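Package: pillscaling
Title: Urban Scaling Analysis of Opioid Pill Distribution Across US
    Commuting Zones
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Implements an urban-scaling analysis of opioid analgesic
    (oxycodone/hydrocodone) pill distribution: aggregation of county-level
    pill counts and populations to commuting zones or core-based statistical
    areas, single-regime and continuous two-regime (single-knot) power-law
    fits of log(pills) on log(population), exhaustive data-driven knot
    selection, AIC model comparison, scaling-regime classification, residual
    diagnostics with outlier flagging and loess smoothing, outlier-exclusion
    sensitivity refits, GeoJSON residual export, and a seeded synthetic-data
    generator with stored ground truth for parameter-recovery validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
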