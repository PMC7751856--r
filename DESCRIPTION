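Package: groceryabm
Title: Spatially Explicit Agent-Based Simulation of Grocery-Shopping Travel
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An empirically-structured, spatially explicit agent-based model of
    weekly grocery-shopping travel in a disinvested urban food environment.
    Stratified household agents (income x age groups) living on a road network
    choose stores and travel modes from group-level probability distributions,
    producing trip logs with network distances, travel modes and shopping
    zones. Includes sample-based Monte Carlo upscaling of a survey sample to a
    census-tract household population, origin-destination shortest-path
    distance tables, reductions to mode-by-distance, store-visit and zone-trip
    summaries, a variance-based (Sobol) global sensitivity analysis engine,
    and a synthetic-city fixture generator calibrated to published aggregate
    travel patterns.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    yaml,
    mgcv,
    data.table,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    ggplot2
Config/testthat/edition: 3
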