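# cpmsize

Minimum sample sizes for **developing and validating clinical
prediction models** with binary or time-to-event outcomes, for study
planners who have summary epidemiology (an outcome prevalence, median
times) but no patient-level data yet: biostatisticians and clinical
researchers sizing observational cohorts for risk models, e.g. in
paediatric oncology, where the package's bundled case study lives.

## What it computes

The core is the multi-criterion methodology of Riley and colleagues.
For `p` candidate predictor parameters and an anticipated Cox–Snell fit
`R²_CS`, the development size must satisfy all of:

1. **shrinkage** — expected uniform shrinkage at least `S` (default 0.9):
   `n ≥ p / ((S − 1) · ln(1 − R²_CS / S))`;
2. **optimism** — apparent-vs-adjusted `R²` difference at most δ
   (default 0.05): the same formula at
   `S₂ = R²_CS / (R²_CS + δ · max R²_CS)`;
3. **risk precision** — the overall risk estimated to ±0.05 with 95%
   confidence: `n ≥ (1.96/0.05)² · φ(1−φ)` for a binary outcome, and
   for survival the smallest `n` whose 95% interval for
   `F(t*) = 1 − exp(−λt*)` (log-normal rate interval
   `λ·exp(±1.96/√E)`, `E = nλf̄` expected events) has half-width ≤ 0.05.

The final size is the maximum of the three ceiled solutions. The
anticipated fit is specified on the Nagelkerke scale and converted via
`R²_CS = R²_N · max R²_CS`, with the outcome-dependent ceiling
`max R²_CS = 1 − exp{2(φ ln φ + (1−φ) ln(1−φ))}` (binary) or
`1 − exp{2e(ln e − 1)}` with `e = λf̄` (survival). When only medians
are published, the person-time rate is approximated by
`λ ≈ p / (p·t_event + (1−p)·t_followup)`.

Alongside: 10/5 events-per-predictor rule-of-thumb sizes, events-based
validation cohort sizes (`⌈100/φ⌉` minimum, `⌈200/φ⌉` desirable), and
sensitivity sweeps over predictor count, anticipated `R²_N`, and the
follow-up/time-point ratio.

## Worked example

The bundled registry (`load_scenarios()`) carries eleven
neuroblastoma/DIPG endpoints with their planning defaults (30
predictors, `R²_N = 0.3`, shrinkage 0.9):

```r
library(cpmsize)
reg <- load_scenarios()

cpm_size(reg[["hr_nb_mort5y"]])
#> Minimum development sample size for 'HR-NB 5-year mortality risk' (binary outcome)
#>   final n          : 1043
#>   expected events  : 521.5  (EPP 17.38 over 30 predictors)
#>   per criterion    : shrinkage 1043, optimism 690, risk_precision 385
```

1043 high-risk neuroblastoma patients are needed, driven by the
shrinkage criterion; that implies 521.5 expected deaths, i.e. 17.38
events per predictor — well above the classical 10-EPP rule, which
would have suggested only `epp_rule_n(10, 30, 0.5)` = 600 patients.
For a time-to-event endpoint the rate is approximated from medians
automatically:

```r
cpm_size(reg[["nb_death_tte"]])
#> Minimum development sample size for 'NB time to death' (time-to-event outcome)
#>   final n          : 1394
#>   expected events  : 209.6  (EPP 6.99 over 30 predictors)
#>   per criterion    : shrinkage 1394, optimism 924, risk_precision 176

validation_size(0.307)   # validating a fixed NB mortality model
#> Validation cohort size (prevalence 0.307)
#>   minimum   (100 events): 326 patients
#>   desirable (200 events): 652 patients

sweep_predictors(reg[["hr_nb_mort5y"]])
#> Sample-size sweep over n_predictors for 'HR-NB 5-year mortality risk'
#>   scenario_id    parameter value final_n   epp
#>  hr_nb_mort5y n_predictors     5     385 38.50
#>  hr_nb_mort5y n_predictors    10     385 19.25
#>  hr_nb_mort5y n_predictors    15     522 17.40
#>  hr_nb_mort5y n_predictors    20     696 17.40
#>  hr_nb_mort5y n_predictors    25     870 17.40
#>  hr_nb_mort5y n_predictors    30    1043 17.38
```

The sweep shows the practical lever: halving the candidate predictors
from 30 to 15 halves the requirement to 522, until the flat
risk-precision criterion (385) forms a floor at small counts.

## Command line

`exec/cpmsize` wraps the same functions:

```sh
cpmsize rate --prevalence 0.307 --median-event-time 24.2 --median-follow-up 60
# 0.0063
cpmsize validate --prevalence 0.169
cpmsize report --out results/ --format csv    # all tables, deterministic
```

## Limitations

Continuous outcomes are out of scope, as is any model fitting or
data-driven estimation of `R²`: inputs are planning assumptions.
A handful of published case-study cells are documented divergences
(rounding-path artefacts in the source tables); see the methods
vignette (`vignettes/sample-size-methods.Rmd`) for the list and for the
validity domain of the survival ceiling.
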