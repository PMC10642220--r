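Package: prevproj
Title: Projection of Risk-Factor Prevalence by Multiple Imputation of Future Survey Waves
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Projects the population prevalence of non-communicable-disease
    risk factors (current smoking, leisure time sedentary lifestyle,
    hypertension, elevated total cholesterol, body-mass-index categories and
    diabetes) from repeated cross-sectional health examination surveys.
    Future survey waves are represented as pseudo-samples whose age and sex
    structure follows a population projection; all of their outcomes, together
    with item and unit non-response in the observed waves, are treated as
    missing data and filled in by chained-equations multiple imputation with
    logistic and polytomous-logistic samplers. Imputation models are chosen by
    the Bayesian information criterion, with restricted cubic splines as an
    alternative to a linear secular trend. Pooled prevalences carry Wilson
    score intervals, and absolute/relative change tables and trend figures are
    produced. A synthetic-data module generates multi-wave surveys with known
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    splines,
    nnet,
    MASS,
    withr,
    jsonlite,
    yaml,
    ggplot2,
    rlang
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
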