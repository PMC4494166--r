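Package: dxrank
Title: Holistic Comparison and Ranking of Diagnostic Tests Across
    Integrated, Partially Overlapping Datasets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for comparing and ranking clinical diagnostic tests when
    each test was measured only in a subset of several small studies.
    Contributing per-study cohorts are merged into one integrated dataset
    with missing cells; tests are ranked by a signal-to-noise separation
    index and by sensitivity/specificity with confidence intervals; missing
    test results are filled by a step-wise imputation engine with k-nearest
    neighbour, linear-model and neural-network backends in supervised or
    unsupervised mode; imputation quality is assessed by leave-one-out
    cross-validation and measured-versus-imputed accuracy distortion; and a
    Bayesian two-group multinomial model with data augmentation estimates
    sensitivity and specificity directly from the incomplete data. A seeded
    synthetic cohort generator reproduces a five-study urothelial-carcinoma
    design (cytology, NMP22, UroVysion FISH, Cxbladder Detect) so the whole
    pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    nnet
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
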