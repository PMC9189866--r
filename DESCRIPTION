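Package: mesamhw
Title: Environmental Sensitivity Mapping of Marine Heatwave Impacts on
    Mediterranean Seagrass
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a categorical environmental-sensitivity mapping
    (MESA) pipeline for marine-heatwave-induced loss of Posidonia oceanica
    ecosystem services. Detects fixed-threshold marine heatwaves (daily sea
    temperature above 24 degrees Celsius for at least five consecutive days,
    May to September) in gridded daily temperature cubes, extracts per-pixel
    severity and recovery metrics, scores them on five-class categorical
    threshold tables, combines impact severity and potential for recovery
    through the MESA susceptibility matrix, scores national exclusive
    economic zones for coastal-hazard and seagrass-dependent-fisheries
    importance, and multiplies susceptibility with importance into
    Very Low to Very High sensitivity classes on a quarter-degree grid-cell
    lattice. Includes a synthetic-data generator that plants heatwave
    events, toy geography, catch tables and coastline-risk tables with
    known ground truth so the full pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    ncdf4,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
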