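Package: phenodd
Title: Temperature-Driven Phenology of Spodoptera frugiperda via Linear
    Degree-Day Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for temperature-driven insect phenology analysis built
    around the linear degree-day model, with defaults and reference tables
    for the fall armyworm (Spodoptera frugiperda). Fits linear
    development-rate models per life stage from constant-temperature
    rearing data, derives lower temperature thresholds and degree-day
    thermal requirements, forecasts adult emergence dates from daily
    min/max temperature series, quantifies evaporation-corrected corn-leaf
    feeding, estimates hatch and larval survival from replicate counts,
    and generates synthetic rearing data with known ground truth for
    pipeline validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
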