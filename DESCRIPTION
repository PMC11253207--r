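Package: nightmtr
Title: Nocturnal Bird Migration Traffic Rates, Wind Decomposition and
    Weather Selectivity from Radar Observations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing nocturnal bird migration recorded by
    vertical-looking and weather radars. Computes migration traffic rates
    (MTR, birds per km per hour) per elevation bin and per night, applies
    Rayleigh-test directionality corrections, interpolates gridded
    atmospheric variables to flight altitude via geopotential height,
    decomposes bird ground speeds into tailwind and airspeed components,
    fits boosted regression trees with cross-validated stagewise tree
    selection to model weather selectivity, and contrasts flight speeds
    between migration seasons with linear mixed models. Includes a
    synthetic radar-world generator with known ground truth so that every
    pipeline stage can be validated without real radar or reanalysis data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    xgboost,
    lme4,
    lmerTest,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
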