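Package: heatstrain
Title: Occupational Heat-Stress Exposure Analysis for Outdoor Worker Case Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates wet-bulb globe temperature (WBGT) from hourly dry-bulb
    temperature and relative humidity using a closed-form wet-bulb
    approximation and a quadratic WBGT regression, detects heat-wave episodes
    (runs of days with maxima at or above an advisory threshold) and tropical
    nights (night minima strictly above 25 degrees C) in station weather
    series, applies ISO-style occupational WBGT exposure limits stratified by
    acclimatization status and metabolic-rate class, and classifies and
    summarizes compensated heat-related illness cases in outdoor workers. A
    seeded synthetic generator for hourly summer weather and worker cohorts
    makes the full pipeline testable without station exports, and a packaged
    47-case table supports end-to-end reproduction of the published cohort
    proportions.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    lubridate,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    withr,
    yaml
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    tidyr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
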