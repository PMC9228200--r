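Package: medopt
Title: Dual RSM/ANN Modelling and Desirability Optimization of Microbial Cultivation Media
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for statistical optimization of fermentation medium
    composition for microbial biocontrol agents. Implements one-factor
    screening statistics (one-way ANOVA and Duncan's multiple range test),
    Box-Behnken designs with coded/natural unit mapping, second-degree
    polynomial response-surface models with full inference, autoencoder-based
    augmentation of small designed-experiment datasets with a multilayer
    perceptron predictor, adjusted-R2 model comparison, and Derringer-Suich
    multi-response desirability optimization over the fitted surfaces. A
    synthetic-data generator reproduces designed experiments from known
    quadratic surfaces so every stage of the workflow is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
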