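Package: voroscan
Title: Small-Area Cluster Analysis with Voronoi Neighborhood Estimation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Small-area spatial epidemiology for settings with limited
    mapping penetration: estimates neighborhood boundaries from named
    point labels via Thiessen (Voronoi) polygons clipped to a study area,
    aggregates gridded population counts and geocoded case line lists to
    the neighborhood level, tests spatial autocorrelation with global and
    local Moran's I under tiered false-discovery-rate control, and
    detects spatial and space-time clusters with the Kulldorff discrete
    Poisson scan statistic with Monte Carlo inference. Includes a
    synthetic study generator emulating an urban firearm-injury
    surveillance study (block-missing hospital records, heterogeneous
    population, embedded risk clusters) so the full pipeline is testable
    without private data, and a verifier for the arithmetic of published
    scan output tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    MASS,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
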