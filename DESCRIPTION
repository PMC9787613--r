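Package: transleaf
Title: Trans-Species Tree Leaf Biomass Estimation
Version: 0.1.0
Authors@R:
    person("Forest", "Biometrics", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Fits and applies trans-species allometric models of individual
    tree dry leaf mass. Log-linear ordinary least squares models combine stem
    diameter, live crown ratio, crown class (as a variable intercept), species
    functional traits (leaf longevity, shade tolerance, wood specific gravity)
    and site climate (mean annual temperature and precipitation). Includes
    Baskerville back-transformation bias correction, backward stepwise AIC
    selection, variance inflation screening, k-fold / leave-one-species-out /
    leave-one-group-out cross-validation with MPE, MAE, MAPE and MAAPE error
    metrics, dominance-analysis variable importance, a packaged 61-species
    trait table and published coefficient sets, a synthetic tree-table
    generator for testing, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
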