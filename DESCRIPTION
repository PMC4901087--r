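Package: cvdle
Title: Life Expectancy With and Without Cardiovascular Disease from
    Panel-Observed Multi-State Cohort Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Fits a continuous-time, non-recoverable illness-death Markov
    model (free of cardiovascular disease, nonfatal cardiovascular disease,
    all-cause death) to panel-observed cohort data with exactly dated deaths,
    using proportional-hazards transition intensities with Gompertz-type age
    dependence and time-dependent covariates carried forward between
    contacts.  Converts fitted intensities into total life expectancy,
    disease-free life expectancy and life expectancy lived with disease at a
    starting age, for arbitrary covariate profiles, with parametric-bootstrap
    percentile intervals and paired between-profile differences.  Includes a
    synthetic cohort generator emulating the baseline-plus-recontact
    observation design of ageing cohorts, harmonised lifestyle covariate
    coding (smoking, vigorous physical activity, body-mass-index and alcohol
    categories), and a pipeline producing per-risk-factor and joint
    favourable-versus-unfavourable lifestyle life-expectancy tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
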