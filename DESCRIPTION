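Package: tideforage
Title: Tidal Regime Switching and Central-Place Foraging Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline linking coastal tidal regime switching to the
    foraging range of a central-place seabird predator. Classifies tide-gauge
    records into diurnal and semidiurnal regimes by counting daily high tides,
    cleans ARGOS satellite tracks with a land mask and a sequential
    maximum-speed filter, zero-offset-corrects 1 Hz time-depth-recorder series
    and detects foraging dives, estimates 100 m depth-integrated currents from
    glider dead-reckoning residuals, compares current bearing distributions
    with the Mardia-Watson-Wheeler uniform-scores test, fits random-intercept
    linear mixed models of foraging distance on tidal covariates, and maps
    utilization with kernel-density 95% contours. Includes a seeded
    synthetic-data generator emulating mixed tides, class-dependent ARGOS
    error, sensor drift and glider navigation so that every stage is testable
    without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    lme4,
    nortest,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    MASS,
    geosphere,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
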