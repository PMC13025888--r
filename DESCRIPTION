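Package: tindiet
Title: Dietary Tin Exposure and Organotin Risk Assessment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for population dietary exposure assessment of tin (Sn) from
    food-surveillance summary data: half-LOD substitution and descriptive
    summaries for left-censored concentration measurements, a deterministic
    P50/P95 scenario grid of estimated daily intakes (EDI) and total hazard
    quotients (THQ) by food item and age group, conservative organotin
    screening, Monte Carlo exposure simulation with percentile-at-TDI
    estimation, and a reverse (minimum organotin conversion fraction)
    statistic. Includes a calibrated synthetic-data generator that
    reproduces published censored-concentration and consumption summaries
    so the full pipeline runs without sample-level study data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
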