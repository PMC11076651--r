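Package: genewrap
Title: Metaheuristic Wrapper Feature Selection for Microarray Expression Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A tested pipeline for two-class microarray gene-expression
    classification: seeded synthetic expression data with realistic
    heavy-tailed per-gene distributions, five per-sample feature-extraction
    methods (Gaussian mixture responsibilities, nonlinear regression
    residuals, k-means profiles, principal components, discrete cosine
    transform), three metaheuristic wrapper feature selectors (harmony
    search, firefly algorithm, elephant herding optimization), eight
    classifier configurations under stratified k-fold cross-validation,
    and a ten-metric confusion-matrix evaluation layer including inverse
    reconstruction of confusion matrices from published accuracy,
    precision and F1 triples.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    yaml,
    e1071,
    ranger,
    rpart,
    xgboost,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS,
    mclust,
    optparse
Config/testthat/edition: 3
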