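Package: noteps
Title: Propensity-Score Confounding Adjustment with NLP-Derived Proxy
    Features from Clinical Notes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for ultra-high-dimensional proxy confounding adjustment in
    new-user cohort studies that link administrative claims with electronic
    health record (EHR) free-text notes. Converts pre-index notes into binary
    patient-level features (n-grams, lexicon concept matching, and embedding
    clusters over word, contextual-word and sentence units), screens features
    by prevalence and by instrumental-variable risk, fits cross-fitted LASSO
    propensity scores over nested covariate sets, applies inverse-probability,
    overlap and matching weights, estimates weighted Cox hazard ratios with
    robust variance, and reports standardized-difference covariate balance for
    candidate and non-candidate features. Includes a synthetic claims+notes
    cohort generator with known latent confounders, note-only confounders and
    planted instrumental variables for method evaluation.
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
    glmnet,
    jsonlite,
    Matrix,
    methods,
    purrr,
    rlang,
    stats,
    stringr,
    survival,
    tibble,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
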