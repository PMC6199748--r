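Package: fjordtrack
Title: Habitat Use and Movement Analysis for Coastal Argos Telemetry
Version: 0.1.0
Authors@R: person("fjordtrack", "developers", role = c("aut", "cre"),
    email = "maintainers@example.org")
Description: An end-to-end pipeline for Argos satellite telemetry of
    extremely coastal marine mammals in glaciated archipelagos.
    Implements speed-distance-angle (SDA) track filtering, a simplified
    particle filter that corrects on-land positions against an
    epoch-specific land mask, hourly along-track interpolation, four-class
    habitat assignment from coastal geometry (glacier fronts, fjords,
    coast, open sea), sea-ice type joining, per-hour movement metrics,
    seasonal occupancy smooths (binomial GAMMs with individual random
    effects and AR1 errors) and movement-metric mixed models. A
    synthetic-data module generates archipelago geometry, behaviour-state
    whale tracks, Argos-like observations and sea-ice fields with known
    ground truth so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    mgcv,
    nlme,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
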