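Package: adcoi
Title: Cost-of-Illness Modelling for Atopic Dermatitis in Romania
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A severity-stratified cost-of-illness pipeline for atopic
    dermatitis, built around the 2022 Romanian burden analysis: seeded
    synthetic patient/caregiver survey generation with exact-mean cost
    calibration and a controllable missing-not-at-random mechanism;
    missingness diagnosis (Little-type MCAR chi-square plus logistic
    missingness regression) and predictive-mean-matching chained-equations
    imputation; extrapolation of survey severity shares to national GBD
    prevalence/incidence counts, hospital discharges and worker counts;
    a four-scenario costing engine (prevalence/incidence crossed with
    survey-reported vs average-prescription treatment costs) covering
    direct medical, direct non-medical and human-capital absenteeism
    costs; and EQ-5D-5L utility scoring with a pluggable value set,
    dimension dichotomization and EQ-VAS summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
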