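Package: gachart
Title: Genetic-Algorithm-Learned Chart-Based Cardiovascular Risk Scores
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Learns interpretable, chart-based 10-year cardiovascular disease
    risk scores with a genetic algorithm operating under monotonicity
    constraints. A risk chart is a grid of ordinal risk bands indexed by
    categorized risk factors (sex, age group, blood pressure, cholesterol,
    waist-to-hip ratio, family history, diabetes, smoking); each chart block
    is a small matrix of risk levels evolved to maximize the area under the
    ROC curve while remaining non-decreasing in blood pressure and
    cholesterol. Includes chromosome validity and repair operators, roulette
    selection, splice crossover, elitist blockwise training ordered by block
    data size, a ratio-based post-hoc modifier, stratified k-fold cross
    validation, a synthetic-cohort simulator with a planted monotone risk
    surface for end-to-end testing, JSON chart serialization, text chart
    rendering, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
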