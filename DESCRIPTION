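Package: calmstreets
Title: Evaluation of Citywide 20 mph Speed-Limit Natural Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reusable, tested pipeline for evaluating citywide speed-limit
    interventions on police-recorded road traffic collision data. Provides
    collision-to-road-network snapping (nearest segment within a distance
    threshold) and zone overlay, annualized collision and casualty rates
    with exact Poisson (Garwood) confidence intervals, percent changes and
    difference-in-differences with delta-method uncertainty, a penalized
    spline (GAM) interrupted-time-series counterfactual for monthly
    casualty counts, and the Elvik exponential speed-injury prediction
    model with a linear traffic-volume adjustment. Includes a synthetic
    data generator that emulates the statistical structure of the real
    data so every stage can be validated without any external download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    mgcv,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
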