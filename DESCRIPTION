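Package: ch4combine
Title: Combining Published Enteric Methane Prediction Equations for Dairy Diets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Evaluates a library of 32 published enteric methane prediction
    equations over dairy ration composition tables, quantifies the
    between-equation spread in predicted emissions, and derives a combined
    prediction equation by fitting a random-intercept linear mixed model
    (REML) to the stacked equation-by-diet prediction table with
    standardized predictors and exact back-transformation to raw units.
    Includes collinearity screening, variance inflation factors,
    leave-one-diet-out cross-validation, leave-one-equation-out sensitivity
    analysis, and a seeded synthetic completion module for the diet
    variables (dry matter intake, energy concentrations, ash) that ration
    composition tables typically omit.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    yaml,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
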