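Package: gwgscreen
Title: Gestational Weight Gain Reference Ranges and Referral-Rule Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds weekly expected gestational weight gain (GWG) ranges from
    the Institute of Medicine total-gain recommendations for each pre-pregnancy
    BMI category, applies +/-2 kg and +/-5 kg dietetic-referral screening rules
    at single and consecutive antenatal visits, and evaluates those rules'
    sensitivity, specificity and likelihood ratios (with 95% confidence
    intervals) for predicting total GWG outside recommendations at 36 weeks'
    gestation. Includes a longitudinal cohort simulator with known latent
    trajectories so every pipeline stage can be tested end to end, plus an
    independent Monte Carlo oracle for the rules' true operating
    characteristics.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    readr,
    rlang,
    yaml,
    stats,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
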