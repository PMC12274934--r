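Package: cvdmicrosim
Title: Dynamic Open-Cohort Microsimulation of Cardiovascular Disease Burden
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A discrete-time, stochastic, open-cohort microsimulation of coronary
    heart disease and stroke for counterfactual risk-factor attribution.
    Distributional (location-scale-shape) trend models are fitted to survey
    records of seven cardiovascular risk factors; rank-persistent individual
    life courses with exposure lags drive lagged relative-risk disease dynamics
    calibrated to input incidence and mortality trends; counterfactual scenarios
    freeze risk-factor distributions at a baseline year; outputs are cases,
    case-years and deaths prevented or postponed, net quality-adjusted life
    years, and net direct and indirect costs, with second-order Monte Carlo
    uncertainty under common random numbers. A synthetic-data module generates
    every model input from presets with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    MASS,
    nnet,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
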