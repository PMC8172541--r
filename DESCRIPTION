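Package: glucowear
Title: Personalized Glucose Excursion Detection and Prediction from
    Noninvasive Wearables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Engineers 69 historical features per 5-minute epoch from
    wrist-wearable sensor streams (heart rate, electrodermal activity, skin
    temperature, triaxial accelerometry, inter-beat intervals), food logs
    and demographics; labels interstitial glucose excursions against a
    personalized rolling 24-hour baseline (PersHigh/PersLow/PersNorm);
    classifies excursions with recursive feature elimination inside
    repeated stratified cross-validation; and predicts 5-minute glucose
    with gradient-boosted trees under leave-one-person-out and
    personalized evaluation, with impurity-based feature-importance
    aggregation. Includes a seeded synthetic cohort generator emulating
    the sensor streams, meal-driven glucose rises, activity dips and
    circadian baseline needed to exercise the pipeline end to end.
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
    nnet,
    purrr,
    ranger,
    readr,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
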