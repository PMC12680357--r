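Package: sacshape
Title: Surrogate Shape Modelling for Spring-Assisted Cranioplasty
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale pipeline for predicting the post-operative head
    shape after spring-assisted cranioplasty in sagittal craniosynostosis.
    Generates synthetic populations of scaphocephalic skull models, applies
    parametric osteotomies and Hookean spring distractors through a
    deterministic quasi-static Laplacian shell simulator, builds statistical
    shape models (PCA on corresponding meshes), and trains tuned multi-output
    regression surrogates that map age, surgical parameters, spring
    parameters and pre-operative shape modes to post-operative shape modes.
    Includes design-of-experiments sampling, rigid and non-rigid ICP template
    correspondence, STL input/output, surface-distance validation maps and
    correlation analysis of prediction error against clinical covariates.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    e1071,
    rpart,
    ranger,
    xgboost,
    lhs
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
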