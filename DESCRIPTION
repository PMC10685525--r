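Package: wtbudget
Title: Water Turnover Prediction and Water-Budget Partitioning from Survey Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Estimates human water turnover from anthropometric, dietary and
    environmental inputs using the prediction equation developed from the
    international doubly labelled water database, and partitions it into
    metabolic, respiratory, transcutaneous and pre-formed water. Includes
    energy-side derivations (calibrated energy intake, predicted basal
    metabolic rate, physical activity level, food quotient, carbon-dioxide
    production, body surface area), restricted cubic spline dose-response
    modelling of water consumption against age, comparison of equation-based
    and dietary-record-based pre-formed water, and a synthetic-data generator
    emulating group-aggregate national nutrition survey records. Ships the
    2016 National Health and Nutrition Survey (Japan) group aggregates as a
    packaged fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
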