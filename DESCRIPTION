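Package: strokeaccess
Title: Drive-Time Accessibility Modelling for Acute Stroke Care Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Grid-based geospatial accessibility analysis for time-critical
    emergency care, built around acute ischaemic stroke. Computes
    minutes-by-road travel-time fields from tiered hospital registries
    (CT-equipped hospitals, stroke-ready hospitals, certified stroke units,
    thrombectomy centres) over a road network, derives drive-time isochrones
    at 5-minute steps up to one hour, masks gridded population rasters to
    produce coverage tables, and classifies every grid cell by the time a
    hub-and-spoke pathway (nearest CT-equipped hospital plus telemedicine)
    would save over direct transfer to a specialised unit, under driving-speed
    and in-hospital-delay scenarios. Includes a synthetic-region generator
    (clustered population raster, settlement-code raster, road network,
    nested facility registry, administrative regions) so the whole pipeline
    is testable without external data, plus urban/rural and state/county
    breakdowns.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    mgcv,
    stats,
    utils,
    grDevices,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
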