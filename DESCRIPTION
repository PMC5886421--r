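Package: stratalife
Title: Stratified Abridged Life Tables with Old-Age Mortality Extrapolation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Life expectancy and years of life lost for disease cohorts with
    selection effects, using the Chiang II abridged life table with sampling
    variance. Mortality schedules may be stratified by time since cohort
    entry (a one-year "select" interval at the entry age followed by
    "ultimate" survivor rates), and incomplete schedules are completed to the
    oldest ages by Gompertz log-linear projection, a constant rate ratio, or
    a constant rate difference relative to a general-population reference
    schedule, with extrapolated rates floored at the reference rates. Also
    provides tabulation of stratified mortality rates from person-level
    cohort records (entry, death and censoring dates), exact Poisson rate
    confidence intervals, annual incidence/prevalence/mortality series with
    quasi-Poisson average-annual-percent-change trends, and a person-level
    cohort simulator for validating the full pipeline by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
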