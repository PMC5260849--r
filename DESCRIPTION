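Package: forestcloud
Title: Cloud-Cover Enhancement over Temperate Forests from Geostationary Imagery
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to quantify preferred cloud formation over large temperate
    forest regions from geostationary visible-channel count imagery. Implements
    an empirical per-pixel clear-sky climatology (steepest section of the
    empirical cumulative distribution function within hour-of-day by 10-day
    bins) with constant-threshold cloud masking, cloud-frequency climatologies
    and forest/non-forest box statistics with bootstrap percentile intervals,
    wind-conditioned composites with 90th-percentile exceedance contours, and a
    squared-sine-with-trend breakpoint fit for quantifying the loss of the
    forest cloud enhancement after storm windthrow. A seeded synthetic-scene
    generator with known ground truth makes every stage testable without
    satellite data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    minpack.lm,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
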