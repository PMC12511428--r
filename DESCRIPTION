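Package: nitrobox
Title: Box Modelling and Proxy Systematics for the Marine Nitrogen Cycle
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the coupling of the marine nitrogen,
    phosphorus and oxygen cycles over geological time. Provides a
    three-box ocean isotope model (surface, oxygen-minimum zone, rest of
    the ocean) with closed- and open-phosphorus configurations, a
    steady-state solver with exact 14N/15N isotopologue bookkeeping, and
    parameter sweeps over upwelling transport and phosphorus inventory or
    input. Companion proxy tools compute carbon-isotope fractionation
    (epsilon_TOC, Delta_CARB, epsilon_P minus Delta_2), sediment-record
    composites and their statistics (record splicing, Delta-15N between
    deep and distal records, organic-carbon accumulation rates, N*,
    age binning, windowed correlations), and a coastal Ekman upwelling
    mass-flux diagnostic for gridded wind-stress fields. Synthetic-data
    generators emulate sediment-record tables, idealized continents and
    wind fields, and noisy box-model observations so every analysis is
    reproducible without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
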