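Package: ricegas
Title: Farm-Scale Greenhouse Gas Accounting for Rice Residue Management
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tier 1/2 greenhouse-gas accounting for four rice crop-residue
    management pathways (open burning, in-situ incorporation, livestock fodder
    with manure return, and biochar) in rice-wheat rotations, together with
    the field-hydrology tooling needed to drive a process-based soil model:
    classification of daily water-level observations into flooded, saturated
    and drained days, selection of dry/median/wet representative fields,
    stochastic construction of multi-year water-table input schedules, and
    aggregation of annual soil CH4/N2O/SOC series with non-soil emissions
    into net CO2-equivalent scenario tables. Includes a synthetic generator
    for field hydrographs and annual soil-flux series, file-level interfaces
    for a daily-time-step biogeochemical model, and a generic
    calibrate-to-tolerance search harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
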