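Package: encar
Title: Ecosystem Natural Capital Accounts from Land-Cover Rasters and Catchment Tables
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A biophysical ecosystem accounting engine for river-basin
    territories. From multi-epoch categorical land-cover rasters, a nested
    catchment hierarchy and tabular use statistics it compiles the four core
    ecosystem natural capital accounts (land cover, water, bio-carbon,
    ecosystem infrastructure), their intensity-of-use and health indices, and
    the integrated total ecosystem capability indicator per socio-ecological
    landscape unit (SELU). Includes a seeded synthetic-watershed generator so
    the full accounting chain is reproducible without external data, plain-text
    raster (ESRI ASCII grid) and CSV input/output, and a deterministic
    end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
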