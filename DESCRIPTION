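Package: accesscape
Title: Raster Travel-Time Accessibility Modelling for Emergency Obstetric Care
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Least-cost-path (friction surface) modelling of geographic access
    to emergency obstetric and neonatal care facilities over raster
    landscapes. Builds a combined land-cover grid from land cover, roads,
    rivers and boat routes; accumulates anisotropic multi-modal travel time
    to the nearest facility under walking, cycling, motorcycle and car
    scenarios with Tobler slope correction of walking speed; classifies
    30-minute travel-time zones and 2-hour catchments; aggregates gridded
    live-birth counts into per-zone and per-council coverage statistics; and
    ranks candidate facility upgrades by the births they newly cover. A
    seeded synthetic-landscape generator emulates the statistical structure
    of the study region so the whole pipeline is testable without external
    geodata.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite,
    yaml,
    mgcv,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
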