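Package: pfdisturb
Title: Disturbance Assessment in Primary and Potential Primary Forests
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Assessment of forest disturbance in documented primary and
    potential primary forests from annual disturbance-year, disturbance-severity
    and forest-mask rasters overlaid on polygon inventories. Delineates
    disturbance and forest patches by rook contiguity with a minimum mapping
    unit, attributes disturbances to the periods predating and postdating each
    inventory's mapping year, and computes area, proportion and mean annual
    rate of area disturbed plus patch-level disturbance severity, stratified by
    country, biogeographical region, EU and continental level. Uncertainty via
    bootstrap percentile confidence intervals, a bootstrap rate-difference test
    and a subsampled Mann-Whitney U severity test, with a mapping-year
    sensitivity analysis. Includes a synthetic-landscape generator with known
    ground truth for validation, plain-text raster (ESRI ASCII grid) and
    GeoJSON polygon input/output, and a country-level comparison of mapped
    against reported primary-forest areas.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mgcv,
    optparse,
    withr
Config/testthat/edition: 3
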