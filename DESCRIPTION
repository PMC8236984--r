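Package: ojipcal
Title: Chlorophyll a, Cell Density and Primary Productivity from OJIP
    Fluorescence Integral Areas
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Non-invasive estimation of phytoplankton chlorophyll a content,
    photosynthetic cell density, and aquatic primary productivity from the
    integral area of fast chlorophyll-fluorescence induction (OJIP)
    transients. Provides instrument-export readers and writers for OJIP
    transients, the integral-area statistic and basic JIP-test descriptors
    (Fo, Fm, Fv/Fm, FJ, FI), linear calibration fitting with Pearson
    correlation significance testing, the methanol-extract chlorophyll a
    absorbance formula, the empirical productivity formula, light/dark-bottle
    oxygen-to-carbon conversion, cross-calibration of OJIP productivity
    estimates against the oxygen method, and a seeded synthetic OJIP
    transient generator for validation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
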