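Package: co2cast
Title: Forecasting the Annual Rise in Atmospheric CO2 from ENSO Sea
    Surface Temperatures and Anthropogenic Emissions
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Statistical forecasting of the annual increment in monthly
    mean atmospheric CO2 concentration at a background observatory (the
    Mauna Loa record is the motivating case) from the April-March mean
    Nino 3.4 sea surface temperature anomaly and annual anthropogenic
    carbon emissions.  Provides gap-aware monthly time-series utilities
    (annual means, increments, in-year growth rates, seasonal adjustment
    factors), combination of observed and seasonal-forecast SST anomaly
    ensembles, calibration of the increment regression by ordinary least
    squares, downscaling of annual forecasts to monthly concentrations,
    counterfactual no-El-Nino attribution, probabilistic forecast
    verification, and a seed-reproducible synthetic-data generator with
    known ground truth for end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
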