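Package: nightcross
Title: Circadian Flight Timing and Water-Barrier Crossing Decisions in
    Diurnally Migrating Songbirds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for GPS tracking of diurnally migrating
    songbirds that intersperse nocturnal flights at open-water barrier
    crossings. Segments fixed-schedule GPS tracks into comparable 12-hour
    day and night intervals, computes great-circle distances, solar
    sunrise/sunset times and per-segment daylight overlap, classifies
    flights over land versus water against a polygon mask, derives
    tailwind-assistance and water:land distance-savings covariates from
    gridded wind fields, and fits a Bayesian mixed-effects logistic
    regression (random intercept per bird) for the decision to cross or
    detour around a waterbody, with Bayes R-squared. Includes a synthetic
    world generator (coastline mask, wind grid, migratory tracks with a
    known crossing law) for end-to-end parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    geosphere,
    igraph,
    jsonlite,
    coda,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    lme4,
    yaml,
    optparse
Config/testthat/edition: 3
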