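Package: edsim
Title: Emergency Department Patient-Flow Simulation and Arrival Forecasting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for capacity planning in hospital emergency departments.
    Generates synthetic hourly patient-arrival data from a nonhomogeneous
    Poisson process with calendar and weather structure, builds model-ready
    feature tables with a causal running mean-arrival-rate covariate, performs
    exhaustive wrapper feature selection and k-fold forecast evaluation
    (MAPE/MAE), and simulates the emergency department as a discrete-event
    queueing network (triage, physician examination, laboratory/X-ray,
    attending specialties, stabilization beds). Experiment machinery includes
    Welch warm-up detection, sequential replication sizing, and a bed-capacity
    sweep that locates the bed count minimizing patient length of stay.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lubridate,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    e1071,
    nnet,
    optparse,
    randomForest,
    readr,
    rpart,
    testthat (>= 3.0.0),
    withr,
    xgboost
Config/testthat/edition: 3
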