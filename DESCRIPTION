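Package: revivr
Title: Reverse-Time Biomarker Models and Dynamic Prediction of Survival
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joint longitudinal-survival analysis built around the revival
    process: a Gaussian model for a biomarker indexed by time-to-death
    (revival time) rather than time-on-study. Provides a seeded synthetic
    cohort generator with exponential marginal survival, visit schedules and
    early-heavy censoring; maximum-likelihood fitting of the revival mean on
    the event, pre-limit and survivor subsets; classical profile-likelihood
    inference on the survival time of individual patients; the implied
    dynamic prediction model (posterior of the survival time given the
    biomarker history) under an exponential marginal and under a
    Kaplan-Meier marginal with an observation-limit atom; and landmark-based
    calibration of the predicted cumulative hazard (rate-factor, exponential
    regression and Cox proportional-hazards calibration).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    survival
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
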