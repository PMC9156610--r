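# Multi-criterion minimum sample size for model development.
#
# Three criteria are computed and the largest size wins:
#   shrinkage       - expected uniform shrinkage of the fitted linear
#                     predictor at least S (default 0.9);
#   optimism        - expected optimism in apparent R2_Nagelkerke at most
#                     `optimism_margin` (default 0.05), i.e. the shrinkage
#                     formula evaluated at S2 = R2cs/(R2cs + margin*maxR2cs);
#   risk_precision  - the overall outcome risk is estimated to within
#                     `risk_margin` (default 0.05) with 95% confidence.
# Each criterion is solved in the reals and ceiled to an integer before
# taking the maximum; this reproduces published sizes to the count.

shrinkage_n <- function(n_predictors, r2_cs, s) {
  n_predictors / ((s - 1) * log(1 - r2_cs / s))
}

criterion_sizes_common <- function(n_predictors, effect, shrinkage_target,
                                   optimism_margin) {
  r2_cs <- effect$r2_cs
  if (r2_cs <= 0) stop("Cox-Snell R-squared must be positive", call. = FALSE)
  if (r2_cs >= shrinkage_target) {
    stop(sprintf(paste0(
      "shrinkage criterion unsatisfiable: anticipated Cox-Snell R2 (%.4f) ",
      "is not below the shrinkage target (%.4f)"), r2_cs, shrinkage_target),
      call. = FALSE)
  }
  s2 <- r2_cs / (r2_cs + optimism_margin * effect$max_r2_cs)
  if (r2_cs >= s2) {
    stop("optimism criterion unsatisfiable: Cox-Snell R2 at or above its ",
         "optimism-adjusted shrinkage", call. = FALSE)
  }
  c(shrinkage = ceiling(shrinkage_n(n_predictors, r2_cs, shrinkage_target)),
    optimism = ceiling(shrinkage_n(n_predictors, r2_cs, s2)))
}

new_cpm_size <- function(criterion_sizes, expected_events, effect, inputs,
                         notes = character()) {
  final_n <- max(criterion_sizes)
  structure(
    list(criterion_sizes = criterion_sizes,
         final_n = as.integer(final_n),
         expected_events = expected_events,
         epp = round_half_up(expected_events / inputs$n_predictors, 2),
         effect = effect,
         inputs = inputs,
         notes = notes),
    class = "cpm_size"
  )
}

#' Minimum development sample size, binary outcome
#'
#' Computes the three-criterion minimum sample size for developing a
#' logistic prediction model: sufficient expected shrinkage, small
#' optimism in apparent fit, and a precise estimate of the overall
#' outcome risk (margin of error `risk_margin` at 95% confidence,
#' \eqn{n \ge (1.96/\delta)^2 \phi(1-\phi)}). The largest of the three
#' is the recommended size.
#'
#' @param n_predictors Number of candidate predictor parameters.
#' @param prevalence Outcome proportion, in (0, 1).
#' @param r2_nagelkerke Anticipated Nagelkerke R-squared (default 0.3);
#'   ignored when `effect` is supplied.
#' @param effect Optionally, an `"effect_size_spec"` from
#'   [nagelkerke_to_cox_snell()]; computed from `prevalence` and
#'   `r2_nagelkerke` when omitted.
#' @param shrinkage_target Required expected shrinkage S, in (0, 1);
#'   default 0.9.
#' @param optimism_margin Maximal tolerated optimism in apparent
#'   R-squared (default 0.05).
#' @param risk_margin Maximal 95% margin of error for the overall risk
#'   estimate (default 0.05).
#' @return An object of class `"cpm_size"` with the per-criterion sizes,
#'   the final size (their maximum), the expected event count and the
#'   implied events per predictor (EPP).
#' @examples
#' develop_binary(30, prevalence = 0.5, r2_nagelkerke = 0.3)
#' @export
develop_binary <- function(n_predictors, prevalence, r2_nagelkerke = 0.3,
                           effect = NULL, shrinkage_target = 0.9,
                           optimism_margin = 0.05, risk_margin = 0.05) {
  n_predictors <- check_count(n_predictors, "n_predictors")
  check_proportion(prevalence, "prevalence")
  check_proportion(shrinkage_target, "shrinkage_target")
  check_positive(optimism_margin, "optimism_margin")
  check_positive(risk_margin, "risk_margin")
  if (is.null(effect)) {
    effect <- nagelkerke_to_cox_snell(r2_nagelkerke,
                                      max_r2cs_binary(prevalence))
  }
  sizes <- c(
    criterion_sizes_common(n_predictors, effect, shrinkage_target,
                           optimism_margin),
    risk_precision = ceiling((Z975 / risk_margin)^2 *
                               prevalence * (1 - prevalence))
  )
  inputs <- list(outcome_kind = "binary", n_predictors = n_predictors,
                 prevalence = prevalence,
                 shrinkage_target = shrinkage_target,
                 optimism_margin = optimism_margin,
                 risk_margin = risk_margin)
  new_cpm_size(sizes, expected_events = max(sizes) * prevalence,
               effect = effect, inputs = inputs)
}

# Smallest n whose 95% interval for the cumulative risk F(t*) =
# 1 - exp(-rate * t*) has half-width <= margin. The rate interval is
# log-normal, rate * exp(+/- 1.96/sqrt(E)) with E = n * rate * meanfup
# expected events; the half-width is monotone decreasing in n, so the
# bound is found by doubling + bisection over the integers.
risk_precision_n_survival <- function(rate, timepoint, mean_follow_up,
                                      risk_margin) {
  half_width <- function(n) {
    se <- Z975 / sqrt(n * rate * mean_follow_up)
    upper <- 1 - exp(-rate * exp(se) * timepoint)
    lower <- 1 - exp(-rate * exp(-se) * timepoint)
    (upper - lower) / 2
  }
  hi <- 1L
  while (half_width(hi) > risk_margin) {
    if (hi >= .Machine$integer.max %/% 2L) {
      stop("risk_precision criterion does not converge; check the rate, ",
           "time point and margin", call. = FALSE)
    }
    hi <- hi * 2L
  }
  lo <- max(1L, hi %/% 2L)
  while (lo < hi) {
    mid <- (lo + hi) %/% 2L
    if (half_width(mid) <= risk_margin) hi <- mid else lo <- mid + 1L
  }
  lo
}

#' Minimum development sample size, time-to-event outcome
#'
#' The survival analogue of [develop_binary()]: the shrinkage and
#' optimism criteria use the survival Cox-Snell ceiling
#' ([max_r2cs_survival()]), and the precision criterion requires the
#' 95% interval for the cumulative risk at the prediction time point,
#' \eqn{F(t^*) = 1 - e^{-\lambda t^*}}, to have half-width at most
#' `risk_margin`, using the log-normal rate interval
#' \eqn{\lambda\,e^{\pm 1.96/\sqrt{E}}} with \eqn{E = n \lambda \bar f}
#' expected events.
#'
#' @inheritParams develop_binary
#' @param rate Incidence rate in events per person-month, e.g. from
#'   [person_time_rate()]. Supplied at full precision by default; pass a
#'   pre-rounded value to emulate published tables that used one.
#' @param prediction_timepoint Time point of the prediction, months.
#' @param mean_follow_up Anticipated mean follow-up of the development
#'   cohort, months.
#' @return An object of class `"cpm_size"`; `expected_events` is
#'   `final_n * rate * mean_follow_up`.
#' @examples
#' r <- person_time_rate(0.307, 24.2, 60)
#' develop_survival(30, rate = r, prediction_timepoint = 24,
#'                  mean_follow_up = 24)
#' @export
develop_survival <- function(n_predictors, rate, prediction_timepoint,
                             mean_follow_up, r2_nagelkerke = 0.3,
                             effect = NULL, shrinkage_target = 0.9,
                             optimism_margin = 0.05, risk_margin = 0.05) {
  n_predictors <- check_count(n_predictors, "n_predictors")
  check_positive(rate, "rate")
  check_positive(prediction_timepoint, "prediction_timepoint")
  check_positive(mean_follow_up, "mean_follow_up")
  check_proportion(shrinkage_target, "shrinkage_target")
  if (is.null(effect)) {
    effect <- nagelkerke_to_cox_snell(
      r2_nagelkerke, max_r2cs_survival(rate, mean_follow_up))
  }
  sizes <- c(
    criterion_sizes_common(n_predictors, effect, shrinkage_target,
                           optimism_margin),
    risk_precision = risk_precision_n_survival(rate, prediction_timepoint,
                                               mean_follow_up, risk_margin)
  )
  expected_events <- max(sizes) * rate * mean_follow_up
  notes <- character()
  if (expected_events < 1) {
    notes <- "fewer than one expected event at the final sample size"
    warning(notes, call. = FALSE)
  }
  inputs <- list(outcome_kind = "time_to_event", n_predictors = n_predictors,
                 rate = rate, prediction_timepoint = prediction_timepoint,
                 mean_follow_up = mean_follow_up,
                 shrinkage_target = shrinkage_target,
                 optimism_margin = optimism_margin,
                 risk_margin = risk_margin)
  new_cpm_size(sizes, expected_events, effect, inputs, notes)
}

#' Development sample size for a planning scenario
#'
#' Dispatches a [prediction_scenario] to [develop_binary()] or
#' [develop_survival()]. For time-to-event scenarios the person-time
#' rate is approximated from the scenario's prevalence and median times
#' via [person_time_rate()], and the scenario's cohort follow-up is used
#' as the mean follow-up.
#'
#' @param scenario A `"prediction_scenario"`.
#' @param n_predictors,r2_nagelkerke,shrinkage_target Overrides of the
#'   scenario's planning parameters.
#' @param rate_digits For time-to-event scenarios, round the
#'   approximated rate to this many decimals before use (e.g. 4 to
#'   emulate a published table); `NULL` (default) keeps full precision.
#' @param ... Further arguments (`optimism_margin`, `risk_margin`)
#'   passed to the underlying calculator.
#' @return An object of class `"cpm_size"` with the scenario id
#'   attached.
#' @examples
#' reg <- load_scenarios()
#' cpm_size(reg[["hr_nb_mort5y"]])
#' @export
cpm_size <- function(scenario, n_predictors = scenario$n_predictors,
                     r2_nagelkerke = scenario$r2_nagelkerke,
                     shrinkage_target = scenario$shrinkage_target,
                     rate_digits = NULL, ...) {
  if (!inherits(scenario, "prediction_scenario")) {
    stop("`scenario` must be a prediction_scenario", call. = FALSE)
  }
  res <- if (scenario$outcome_kind == "binary") {
    develop_binary(n_predictors, scenario$prevalence,
                   r2_nagelkerke = r2_nagelkerke,
                   shrinkage_target = shrinkage_target, ...)
  } else {
    rate <- person_time_rate(scenario$prevalence,
                             scenario$median_time_to_event,
                             scenario$median_follow_up)
    if (!is.null(rate_digits)) rate <- round(rate, rate_digits)
    develop_survival(n_predictors, rate,
                     prediction_timepoint = scenario$prediction_timepoint,
                     mean_follow_up = scenario$study_follow_up,
                     r2_nagelkerke = r2_nagelkerke,
                     shrinkage_target = shrinkage_target, ...)
  }
  res$scenario_id <- scenario$id
  res$label <- scenario$label
  res
}

#' Events per predictor implied by a sample size
#'
#' @param n Sample size.
#' @param prevalence Outcome proportion.
#' @param n_predictors Number of candidate predictor parameters.
#' @return `n * prevalence / n_predictors`, rounded half-up to 2
#'   decimals.
#' @examples
#' epp_from_n(1043, 0.5, 30)  # 17.38
#' @export
epp_from_n <- function(n, prevalence, n_predictors) {
  check_positive(n, "n")
  check_proportion(prevalence, "prevalence", open = FALSE)
  n_predictors <- check_count(n_predictors, "n_predictors")
  round_half_up(n * prevalence / n_predictors, 2)
}

#' @export
print.cpm_size <- function(x, ...) {
  hdr <- if (!is.null(x$label)) sprintf(" for '%s'", x$label) else ""
  cat(sprintf("Minimum development sample size%s (%s outcome)\n",
              hdr, gsub("_", "-", x$inputs$outcome_kind)))
  cat(sprintf("  final n          : %d\n", x$final_n))
  cat(sprintf("  expected events  : %.1f  (EPP %.2f over %d predictors)\n",
              x$expected_events, x$epp, x$inputs$n_predictors))
  cat("  per criterion    :",
      paste(sprintf("%s %d", names(x$criterion_sizes), x$criterion_sizes),
            collapse = ", "), "\n")
  for (n in x$notes) cat("  note: ", n, "\n", sep = "")
  invisible(x)
}

#' @export
summary.cpm_size <- function(object, ...) {
  structure(object, class = c("summary.cpm_size", "cpm_size"))
}

#' @export
print.summary.cpm_size <- function(x, ...) {
  print.cpm_size(x, ...)
  cat("  anticipated fit  : R2_Nagelkerke", format(x$effect$r2_nagelkerke),
      "-> Cox-Snell", sprintf("%.4f", x$effect$r2_cs),
      sprintf("(max %.4f)\n", x$effect$max_r2_cs))
  inp <- x$inputs
  cat(sprintf("  criteria set-up  : shrinkage >= %g, optimism <= %g, risk margin %g\n",
              inp$shrinkage_target, inp$optimism_margin, inp$risk_margin))
  if (inp$outcome_kind == "time_to_event") {
    cat(sprintf("  rate             : %.6g events/person-month; t* = %g mo, mean follow-up %g mo\n",
                inp$rate, inp$prediction_timepoint, inp$mean_follow_up))
  } else {
    cat(sprintf("  prevalence       : %g\n", inp$prevalence))
  }
  invisible(x)
}

#' @export
as.data.frame.cpm_size <- function(x, ...) {
  data.frame(
    scenario_id = if (is.null(x$scenario_id)) NA_character_ else x$scenario_id,
    outcome_kind = x$inputs$outcome_kind,
    n_shrinkage = unname(x$criterion_sizes["shrinkage"]),
    n_optimism = unname(x$criterion_sizes["optimism"]),
    n_risk_precision = unname(x$criterion_sizes["risk_precision"]),
    final_n = x$final_n,
    expected_events = x$expected_events,
    epp = x$epp,
    stringsAsFactors = FALSE
  )
}
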