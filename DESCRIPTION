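Package: phenosow
Title: Remote-Sensing Phenology, Sowing-Date Retrieval and Reduced
    CERES-Style Maize Growth Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Retrieves grid-level maize sowing dates from harmonic models of
    NDVI time series constrained by dekad-encoded start-of-season phenology,
    drives a reduced CERES-style daily crop and soil-water simulator
    (Priestley-Taylor evapotranspiration, tipping-bucket water balance,
    radiation-use-efficiency growth) with them, and evaluates phenology,
    yield and evapotranspiration agreement at grid and regional scales,
    including a +/-30-day sowing-shift sensitivity experiment. Ships a
    seeded synthetic-scenario generator (weather, NDVI with noise, dropouts
    and false pre-season peaks, WaPOR-convention phenology dekads, reported
    regional yields) so the whole pipeline runs and is testable at desk
    scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    withr,
    yaml,
    rlang
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
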