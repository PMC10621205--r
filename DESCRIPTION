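Package: accelbudget
Title: Behavior Classification and Diel Activity Budgets from
    Tri-Axial Accelerometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for turning raw tri-axial accelerometer recordings from
    small nocturnal mammals into classified behavior time series and diel
    activity budgets. Provides window segmentation and a 44-statistic
    feature set (including dynamic body acceleration and ODBA), class
    balancing and train/test evaluation of linear support vector machine,
    decision tree and random forest classifiers across window sizes,
    solar-altitude light-phase and lunar illumination annotation, activity
    budget tables, and generalized linear mixed models of budget
    proportions with AIC family selection, Wald chi-square tests,
    variance inflation factors and conditional R-squared. Includes a
    synthetic-deployment generator with known ground truth for validating
    every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    rpart,
    randomForest,
    lme4,
    sandwich,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    car,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
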