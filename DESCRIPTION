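Package: hccea
Title: Markov Cohort Cost-Effectiveness Modelling of First-Line Systemic
    Therapy in Unresectable Hepatocellular Carcinoma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs pseudo individual-patient data from digitized
    Kaplan-Meier curves with numbers-at-risk tables, fits and selects
    parametric survival models by AIC, and evaluates a three-state Markov
    cohort model (progression-free, progressed, dead) comparing atezolizumab
    plus bevacizumab with sorafenib in unresectable hepatocellular carcinoma:
    3-week cycles, half-cycle correction, 3% annual discounting, background
    mortality from a life table, full cost and utility accounting, long-term
    survival scenarios with a cure assumption, deterministic and probabilistic
    sensitivity analyses, cost-effectiveness acceptability curves, and
    price-reduction threshold search.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    flexsurv,
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
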