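Package: paleorange
Title: Temporal Richness to Range-Size Analysis from Sedimentary DNA Community Tables
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing how plant taxonomic richness relates to mean
    geographic range-size through time in multi-lake sedimentary ancient DNA
    (sedaDNA) metabarcoding datasets. Provides depth standardisation by
    rarefaction resampling, range-size estimation by area of occupancy (AOO,
    occupied-lake counts) and extent of occurrence (EOO, equal-area grid cells
    overlapping the convex hull of occupied lakes), moving time-window linear
    regressions of richness on mean range-size with posterior slope
    simulation, multiple-site Jaccard turnover as a biotic heterogeneity
    proxy, binomial regressions linking the relationship sign to cushion-plant
    and tree abundance, and family-level positive co-occurrence networks with
    exact modularity community detection. A synthetic multi-lake community
    generator with a known occupancy-richness coupling supports end-to-end
    validation of the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite,
    yaml,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    geosphere,
    mgcv,
    MASS
Config/testthat/edition: 3
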