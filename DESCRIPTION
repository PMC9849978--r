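Package: spaccess
Title: Network-Based Walking Accessibility of Urban Health Services
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Spatial-justice analysis of access to health facilities in a city:
    point-pattern statistics (average nearest neighbour ratio), global Moran's I
    spatial autocorrelation of block-level deprivation, quartic-kernel density
    surfaces with a standard-distance bandwidth rule, and network service areas
    (walking-time isochrones) overlaid on census blocks to tabulate population
    with and without access by sex and age band. Includes a reproducible
    synthetic-city generator (jittered grid streets, log-normal population,
    spatially autocorrelated deprivation field, configurable facility point
    patterns) so the whole pipeline is testable without external GIS data.
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
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
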