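Package: healthineq
Title: Socio-Economic Inequality Accounting for Excess Weight in Survey Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for measuring and decomposing socio-economic inequality in
    excess weight (and other bounded health outcomes) from individual-level
    survey records. Provides survey-weight construction (inverse probability
    weighting for outcome non-response and raking to population margins),
    weighted fractional ranks over ordered deprivation scales, the Erreygers
    corrected and Wagstaff normalised concentration indices with bootstrap or
    delta-method inference, and a Shapley decomposition of the dissimilarity
    index of model-predicted outcome probabilities across explanatory factors.
    Includes a synthetic-data generator emulating the structure of an English
    national health examination survey so the full pipeline can be exercised
    and validated against analytic ground truth without access to restricted
    microdata.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    jsonlite,
    ggplot2,
    generics,
    glmnet,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    broom,
    withr
Config/testthat/edition: 3
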