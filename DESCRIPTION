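Package: cortexELM
Title: Cortical Morphometry Classification with Extreme Learning Machines
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Classification of neurodevelopmental disorders from structural-MRI
    cortical morphometry feature tables (cortical thickness, surface area,
    gray-matter volume, folding index and intrinsic curvature over the 68
    Desikan-Killiany parcels). Implements Fisher-score feature ranking,
    sequential forward selection, a single-hidden-layer extreme learning
    machine trained by minimum-norm least squares, support vector machine
    baselines with grid search, leave-one-out cross-validation,
    ROC/AUC analysis, permutation-test significance assessment and a
    synthetic two-class cohort generator with closed-form Bayes accuracy
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS,
    pROC,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
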