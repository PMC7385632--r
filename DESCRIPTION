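Package: geoherb
Title: Ecological Suitability and Quality Regionalization for Medicinal Plants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for delineating production regions of medicinal plants from
    environmental raster layers and occurrence records. Provides an ESRI ASCII
    grid toolkit, a correlated synthetic-landscape generator, pairwise
    correlation screening of environmental factors, a from-scratch
    presence-background maximum-entropy niche model with L1-regularized
    coordinate ascent (cross-validation, percent contribution, permutation
    importance, response curves), natural-breaks classification of suitability
    with per-zone area tables, stepwise regression of compound contents on
    ecological factors projected back onto rasters, and an overlay step that
    intersects optimum suitability with top content grades to map high-quality
    production zones.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
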