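Package: climscreen
Title: Climate-Envelope Screening of Drought- and Cold-Tolerant Species
    from Occurrence Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for preliminary screening of drought- and
    cold-tolerant woody species from georeferenced occurrence records and
    bioclimatic rasters. Occurrence tables are cleaned and spatially thinned
    to one record per grid cell per species, precipitation of the driest
    quarter (PDQ, mm) and minimum temperature of the coldest month
    (MTCM, degrees C) are extracted at each point, and species are profiled
    by their median climate, clustered in median-climate space, and
    classified as candidate tolerant species by strict percentile thresholds
    on the species medians, with a multi-percentile sensitivity analysis and
    Mann-Whitney validation of group separation. Moran's I diagnostics check
    for residual spatial sampling bias. A synthetic-data module generates
    virtual climate surfaces and virtual species with known (planted)
    tolerance structure so that every stage is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    jsonlite,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
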