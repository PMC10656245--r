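Package: rangecap
Title: Carrying Capacity and Utilization Intensity of Cold Dryland Rangelands
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for assessing grazing carrying capacity, grazing
    potential and utilization intensity in cold, high-mountain rangelands.
    Computes metabolizable energy requirements (MER) of livestock and wild
    herbivores from allometric field-metabolic-rate scaling and seasonal
    census tables; builds metabolizable energy content (MEC) maps from
    standing-biomass rasters, vegetation-community forage parameters and
    exclosure-derived productivity ratios; derives seasonal pasture
    accessibility from fractional snow cover and elevation; and combines
    supply and demand into per-grazing-area utilization rates, carrying
    capacities and sustainability classes under a set of scenarios. Includes
    a synthetic-landscape generator with known ground truth so the whole
    pipeline is testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    mgcv,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
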