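Package: droughtimpact
Title: Drought Severity Indexing and Drought-Attributable Suicide
    Projection Under Climate Change Scenarios
Version: 0.1.0
Authors@R:
    person("Analysis", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for climate-change health impact assessment of drought
    and suicide. Computes a modified Hutchinson Drought Severity Index
    (six-month rolling rainfall totals expressed as calendar-month
    percentiles over a rolling 30-year look-back, rescaled to [-4, 4]),
    tracks mild- and full-drought spells, fits a Poisson time-series
    regression of monthly suicide counts on log drought duration with
    age-sex-region stratification, spline trend and season terms and a
    population offset, projects future drought exposure by applying
    GCM/RCP rainfall percentage-change deltas to a cycled baseline
    climate, and computes drought-attributable suicide numbers per annum
    with Monte Carlo empirical confidence intervals. Includes a seeded
    synthetic-data generator emulating the statistical structure of the
    rainfall, population and suicide panels the analysis assumes, so the
    whole pipeline is testable without restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    mgcv,
    splines,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
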