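Package: screenkit
Title: Lab Information Management for High-Throughput Screening Facilities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Core lab-information-management functionality for shared
    small-molecule and RNAi high-throughput screening (HTS) facilities:
    screening-library inventory with versioned contents and a per-well
    volume ledger for library copies; screen-result storage with raw and
    derived data columns, positives classification, cross-screen
    comparison tables and per-plate heat-map matrices; the complete
    cherry-pick request workflow from screener picks through pool
    deconvolution, volume reservation, constrained plate mapping and
    liquid-handler mapping-file export; a tiered reciprocity-based data
    sharing policy; an append-only activity audit trail; and a
    deterministic synthetic-data generator plus a command-line entry
    point binding the modules to files on disk.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    readxl,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
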