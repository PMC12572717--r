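Package: pdcmarkov
Title: Markov Modeling of Long-Term Medication Adherence from Pharmacy Claims
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for modeling and predicting long-term adherence to chronic
    oral therapy (direct oral anticoagulants in particular) from pharmacy
    dispensing claims. Computes gap-adjusted proportion of days covered (PDC)
    over consecutive 90-day windows with carry-over for early refills, agent
    switching and hospitalization credit; maps PDC to a 10-level ordinal
    adherence state; fits first-order proportional-odds Markov transition
    models with restricted-cubic-spline covariate effects by maximum
    likelihood; derives per-patient state occupancy probabilities and mean
    time in state by recursive unconditioning; and provides calibration,
    discrimination (SOP distribution width with bootstrap validation) and
    absolute-error diagnostics. Includes a synthetic cohort generator with a
    known transition model so the whole pipeline can be exercised and
    validated without access to registry data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Rcpp,
    jsonlite,
    yaml,
    mgcv,
    ggplot2,
    rlang
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    MASS
Config/testthat/edition: 3
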