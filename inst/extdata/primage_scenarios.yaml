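# PRIMAGE case-study scenario registry: clinical endpoints for
# neuroblastoma (NB), high-risk neuroblastoma (HR-NB) and diffuse
# intrinsic pontine glioma (DIPG).
#
# Prevalences are stored at the precision reported in the source
# epidemiology text, not at the rounded precision of the summary table:
# in particular NB relapse/progression is 0.2575 (text: 25.75%), not the
# tabulated 0.258 — the derived 10-events-per-predictor size 1166 is only
# reproducible from 0.2575.
#
# All times are months. Planning defaults (n_predictors 30,
# r2_nagelkerke 0.3, shrinkage_target 0.9) are applied at load time and
# deliberately not repeated here.
- id: nb_mort5y
  label: "NB 5-year mortality risk"
  tumour: NB
  outcome_kind: binary
  prevalence: 0.307
- id: nb_relapse
  label: "NB relapse/progression risk"
  tumour: NB
  outcome_kind: binary
  prevalence: 0.2575
- id: nb_death_tte
  label: "NB time to death"
  tumour: NB
  outcome_kind: time_to_event
  prevalence: 0.307
  median_time_to_event: 24.2
  median_follow_up: 60
  prediction_timepoint: 24
  study_follow_up: 24
- id: hr_nb_mort5y
  label: "HR-NB 5-year mortality risk"
  tumour: HR-NB
  outcome_kind: binary
  prevalence: 0.5
- id: hr_nb_relapse5y
  label: "HR-NB 5-year relapse/progression risk"
  tumour: HR-NB
  outcome_kind: binary
  prevalence: 0.408
- id: hr_nb_relapse_tte
  label: "HR-NB time to relapse/progression"
  tumour: HR-NB
  outcome_kind: time_to_event
  prevalence: 0.561
  median_time_to_event: 19.08
  median_follow_up: 72.12
  prediction_timepoint: 24
  study_follow_up: 24
- id: dipg_mort1y
  label: "DIPG 1-year mortality risk"
  tumour: DIPG
  outcome_kind: binary
  prevalence: 0.45
- id: dipg_mort2y
  label: "DIPG 2-year mortality risk"
  tumour: DIPG
  outcome_kind: binary
  prevalence: 0.169
- id: dipg_prog1y
  label: "DIPG 1-year progression risk"
  tumour: DIPG
  outcome_kind: binary
  prevalence: 0.235
- id: dipg_death_tte
  label: "DIPG time to death"
  tumour: DIPG
  outcome_kind: time_to_event
  prevalence: 0.169
  median_time_to_event: 11.4
  median_follow_up: 24
  prediction_timepoint: 24
  study_follow_up: 24
- id: dipg_prog_tte
  label: "DIPG time to progression"
  tumour: DIPG
  outcome_kind: time_to_event
  prevalence: 0.235
  median_time_to_event: 7.7
  median_follow_up: 12
  prediction_timepoint: 12
  study_follow_up: 12
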