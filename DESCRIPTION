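Package: aquaindex
Title: Weighted Arithmetic Water Quality Index Assessment for Piped Supply Water
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing drinking-water quality from multi-parameter
    monitoring tables: the weighted arithmetic Water Quality Index (WQI) with
    grade classification against the IS 10500 drinking-water standard, zone- and
    ward-wise summary statistics with permissible-limit exceedance rates,
    inverse-distance-weighted (IDW) spatial interpolation of parameter surfaces
    with ESRI ASCII grid export, and a seeded truncated-normal generator that
    emulates a three-zone, 67-ward urban sampling design from published summary
    statistics. Includes an end-to-end pipeline from sample table to report.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    readr,
    yaml,
    geosphere,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
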