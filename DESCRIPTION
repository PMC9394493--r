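Package: recruitrisk
Title: Dynamic Landmark Prediction of Attrition from Military Recruit Training
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for dynamically updated prediction of dropout from a
    24-week military recruit training programme. Implements landmarking with
    a stacked Cox proportional-hazards supermodel over weekly landmarks,
    time-varying self-reported health covariates with landmark interactions,
    last-observation-carried-forward completion, left truncation, Breslow
    baseline hazards centred on a reference subject, incident/dynamic
    time-dependent ROC/AUC with Youden-optimal thresholds, repeated k-fold
    cross-validation, and a calibrated synthetic cohort generator emulating
    the baseline distributions, weekly Likert trajectories, dropout hazard,
    and missingness patterns of a real recruit cohort so the whole pipeline
    is testable without access to the original data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    survival,
    zoo,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
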