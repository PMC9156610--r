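# Independent oracle routes used to cross-check the closed-form
# criteria. These deliberately avoid the package's algebra:
#  - the shrinkage implied by a sample size is solved from its implicit
#    definition S = 1 + p / (n * ln(1 - R2cs/S)) with uniroot, and the
#    smallest adequate n is found by scanning the integers;
#  - the survival risk-precision bound is found by a plain linear scan;
#  - person-time rates are built from an explicit pseudo-cohort.
#
# fixtures/survival_sizes_synthetic_oracle.csv is a synthetic fixture:
# the four time-to-event scenario sizes computed once with these oracle
# routes (at 30 predictors, Nagelkerke R2 0.3, shrinkage 0.9) and
# frozen, so later refactors of the package are checked against an
# unchanging reference.

oracle_svh <- function(n, n_predictors, r2_cs) {
  f <- function(S) S - 1 - n_predictors / (n * log(1 - r2_cs / S))
  tryCatch(
    stats::uniroot(f, c(r2_cs + 1e-9, 1 - 1e-12), tol = 1e-12)$root,
    error = function(e) 0  # no admissible shrinkage at this n
  )
}

oracle_smallest_n <- function(target, n_predictors, r2_cs, start = 2L) {
  n <- start
  while (oracle_svh(n, n_predictors, r2_cs) < target) n <- n + 1L
  n
}

oracle_risk_precision_survival <- function(rate, timepoint, mean_follow_up,
                                           margin = 0.05) {
  n <- 1L
  repeat {
    se <- 1.96 / sqrt(n * rate * mean_follow_up)
    hw <- ((1 - exp(-rate * exp(se) * timepoint)) -
             (1 - exp(-rate * exp(-se) * timepoint))) / 2
    if (hw <= margin) return(n)
    n <- n + 1L
  }
}

# Explicit-cohort person-time rate: E events each observed for the
# median event time, N - E censored at the median follow-up.
oracle_cohort_rate <- function(prevalence, t_event, t_followup, N = 1e6) {
  events <- prevalence * N
  events / (events * t_event + (N - events) * t_followup)
}

# Full oracle development size for a time-to-event scenario.
oracle_develop_survival <- function(rate, timepoint, mean_follow_up,
                                    n_predictors = 30, r2n = 0.3,
                                    shrinkage = 0.9, margin = 0.05) {
  e <- rate * mean_follow_up
  max_r2 <- 1 - exp(2 * e * (log(e) - 1))
  r2_cs <- r2n * max_r2
  s2 <- r2_cs / (r2_cs + margin * max_r2)
  c(shrinkage = oracle_smallest_n(shrinkage, n_predictors, r2_cs),
    optimism = oracle_smallest_n(s2, n_predictors, r2_cs),
    risk_precision = oracle_risk_precision_survival(rate, timepoint,
                                                    mean_follow_up, margin))
}

# Vectorised wrapper (the exported function is scalar by contract).
max_r2cs_binary_v <- function(p) vapply(p, max_r2cs_binary, numeric(1))

oracle_fixture <- function() {
  utils::read.csv(test_path("fixtures",
                            "survival_sizes_synthetic_oracle.csv"),
                  colClasses = c(rate_4dp = "character"))
}
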