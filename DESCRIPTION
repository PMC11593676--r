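Package: steroidome
Title: Steroidomic Case-Control Analysis with Enzyme-Ratio Panels,
    Sign-Trend Meta-Statistics and OPLS Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for case-control analysis of comprehensive serum
    steroid panels ("steroidomes") measured on molar scales. Provides a
    declarative registry of 81 steroid analytes and the enzyme-activity
    molar-ratio panels built from them, Box-Cox power transformation
    toward normality, two-factor ANOVA screening with partial
    eta-squared and severity-index correlations, a one-sample
    signed-rank trend meta-statistic over panels of
    significance-direction codes (Pratt zero handling, tie-corrected
    variance, continuity correction), and an OPLS discriminant model
    with VIP predictor selection, Hotelling score screening,
    venetian-blind cross-validation and a log-likelihood-ratio
    probability link. Includes a log-normal steroidome simulator with
    known ground truth for power and calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    nortest,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
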