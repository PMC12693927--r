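Package: microclim
Title: Greenhouse Microclimate Suitability Analysis for Protected Crops
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to characterise the microclimate of low-tech greenhouses
    over a crop production cycle: vapor pressure deficit computation from
    air temperature and relative humidity, rule-based classification of
    5-minute sensor records against stage- and period-specific suitability
    thresholds, time-in-category aggregation and critical-driver
    decomposition, majority-rule daily microclimate status, classification
    trees with cost-complexity pruning tuned by rolling-origin
    cross-validation and the 1-SE rule, iterative tree-ensemble imputation
    of sensor gaps with out-of-bag NRMSE convergence, and descriptive,
    comparative and economic summaries. A synthetic-data generator emulates
    quadrant sensor networks with diurnal structure, spatial offsets and
    realistic missingness so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    rpart,
    withr
Config/testthat/edition: 3
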