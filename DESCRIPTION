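Package: stepcot
Title: Step-Selection Analysis and Cost-of-Transport Energetics for
    Terrestrial Dispersal Tracks
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing habitat selection and energetic efficiency of
    terrestrially dispersing animals from dual-resolution GPS tracks. Provides
    a synthetic generator of habitat rasters, digital elevation models and
    correlated-random-walk tracks with planted selection coefficients; track
    discretization into 5-minute steps, roost extraction and dispersal-day
    classification; step-selection analysis with gamma/von Mises movement
    kernels, matched case-control strata and a from-scratch conditional
    logistic regression with Wald inference and relative selection strength;
    a 4-state hidden Markov movement classifier; and a per-second locomotion
    energetics model (speed- and incline-dependent oxygen consumption)
    aggregated into a cost of transport per 50 m net displacement, with
    per-habitat linear models and contrasts.
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
    survival,
    withr
Config/testthat/edition: 3
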