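Package: asgmrisk
Title: Global Exposure, Health Risk and Valuation of Mercury Emissions from
    Artisanal and Small-Scale Gold Mining
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An exposure-risk-valuation framework for atmospheric mercury
    emitted by artisanal and small-scale gold mining (ASGM). Couples annual
    emission series to a reduced-complexity six-compartment global mercury
    cycle with legacy re-emission, diagnoses the ASGM share of atmospheric
    deposition, plankton methylmercury and soil mercury by scenario
    differencing, propagates the shares through dietary methylmercury intake
    (seafood, freshwater fish, rice) to IQ decrements in newborns and fatal
    heart attacks in adults, monetizes the endpoints with earning-loss and
    value-of-statistical-life coefficients transferred across countries by
    PPP income, and compares discounted losses against gold-mining revenue.
    Includes a synthetic world generator so the full pipeline runs without
    external inventories.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2,
    readr
Config/testthat/edition: 3
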