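Package: desertrefugia
Title: Physiological Climate-Change Impacts and Refugia for Desert Birds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, seeded pipeline for assessing climate-change
    impacts on desert birds from physiological first principles. Monthly
    gridded climate is downscaled to hourly microclimates for the hottest
    month; a steady-state two-node heat and water balance model of a perched
    bird, with an ordered thermoregulatory cascade (sleeked plumage, postural
    stretching, raised flesh conductivity, coupled hyperthermia and panting)
    and shade-shifting behaviour, yields total evaporative water loss (TEWL)
    and acute dehydration risk (ADR). Climate-change impact is the overlap of
    kernel density estimates of current versus future yearly values; desert
    bird diversity is rarity-weighted richness over Area-of-Habitat refined
    ranges; refugia are identified per desert realm with fixed or floating
    percentile thresholds and intersected with protected areas. A synthetic
    data generator provides seeded climate grids, species ranges and
    landscapes with the statistical structure the analysis assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
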