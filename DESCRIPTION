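Package: cpmsize
Title: Sample Size for Developing and Validating Clinical Prediction Models
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Minimum sample size calculations for clinical prediction
    models with binary or time-to-event outcomes, following the
    multi-criterion (shrinkage, optimism, risk-precision) methodology of
    Riley and colleagues, together with classical events-per-predictor
    rules of thumb, events-based validation cohort sizes, a person-time
    incidence-rate approximation from prevalence and median times, and
    sensitivity sweeps over predictor count, anticipated Nagelkerke R2
    and the follow-up/time-point ratio. Ships a registry of eleven
    paediatric-oncology planning scenarios (neuroblastoma and diffuse
    intrinsic pontine glioma endpoints) as a worked case study, and a
    command-line interface for batch reporting.
License: MIT
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
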