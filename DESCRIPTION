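Package: chamoisdem
Title: Demographic Analysis of Alpine Chamois Vital Rates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates and models sex- and age-specific vital rates of an
    Alpine chamois (Rupicapra rupicapra) population from annual block-count
    data. Raw counts with partially classified animals are reassigned and
    adjusted for undercounting, filtered with a state-space (Kalman) model to
    separate observation from process error, and converted into ratio-based
    birth rate, kid, female and male survival, and log population growth rate.
    Vital rates are regressed on lagged own abundance, red deer abundance and
    seasonal precipitation via an AICc-ranked candidate set of autoregressive
    linear models with Akaike-weight averaging, collinearity and
    autocorrelation diagnostics, bootstrap optimism-corrected RMSE and robust
    refits. Indirect effects of red deer abundance on chamois growth, mediated
    by each vital rate, are quantified with three-variable path models
    (chi-square, RMSEA, AIC). A configurable age-structured simulator
    generates true trajectories and observed count tables so every stage can
    be validated against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    MASS,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    car,
    lmtest,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
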