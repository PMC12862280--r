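Package: floodlisa
Title: Spatial Clustering of Flood Risk, Neighborhood Inequality, and
    Chronic Disease Prevalence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tract-level spatial analysis of property flood risk against
    measures of racial and economic inequality and chronic-condition
    prevalence. Builds queen-contiguity spatial weights from polygon
    geometry, computes the Index of Concentration at the Extremes (three
    variants), flood-risk property proportions, grouped-data Gini
    coefficients, and the Index of Dissimilarity, and fits univariate and
    bivariate local Moran's I (LISA) with conditional-permutation
    inference and high-high/low-low/high-low/low-high cluster typology.
    Includes a seeded synthetic census-tract generator with controllable
    spatial autocorrelation and plantable bivariate clusters, cluster
    demographic profiling with Welch t-tests and rural-urban commuting
    area cross-tabulations, and an end-to-end pipeline with CSV, GeoJSON,
    and GAL interchange.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
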