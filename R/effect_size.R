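#' Maximum Cox-Snell R-squared for a binary outcome
#'
#' The Cox-Snell pseudo R-squared of a logistic model cannot reach 1; its
#' ceiling depends only on the outcome prevalence, through the likelihood
#' of the intercept-only (null) model:
#' \deqn{\max R^2_{CS} = 1 - \exp\{2(\phi\ln\phi + (1-\phi)\ln(1-\phi))\}}
#' where \eqn{\phi} is the outcome proportion. The ceiling is symmetric in
#' \eqn{\phi \leftrightarrow 1-\phi}, peaks at 0.75 for \eqn{\phi = 0.5},
#' and tends to 0 as the outcome becomes rare.
#'
#' @param prevalence Outcome proportion, strictly between 0 and 1.
#' @return The ceiling of the Cox-Snell R-squared, a value in (0, 1).
#' @seealso [max_r2cs_survival()], [nagelkerke_to_cox_snell()]
#' @examples
#' max_r2cs_binary(0.5)   # 0.75
#' max_r2cs_binary(0.307)
#' @export
max_r2cs_binary <- function(prevalence) {
  check_proportion(prevalence, "prevalence")
  ll0 <- prevalence * log(prevalence) + (1 - prevalence) * log(1 - prevalence)
  1 - exp(2 * ll0)
}

#' Maximum Cox-Snell R-squared for a time-to-event outcome
#'
#' For survival models the analogous ceiling is driven by the expected
#' number of events per subject, \eqn{e = \lambda \bar f} (incidence rate
#' times mean follow-up), through the per-subject null log-likelihood of
#' an exponential event process:
#' \deqn{\max R^2_{CS} = 1 - \exp\{2 e (\ln e - 1)\}}
#'
#' @param rate Incidence rate in events per person-month, positive.
#' @param mean_follow_up Expected mean follow-up of the development
#'   cohort, in months.
#' @return The ceiling of the Cox-Snell R-squared, a value in (0, 1).
#' @examples
#' max_r2cs_survival(rate = 0.0063, mean_follow_up = 24)
#' @export
max_r2cs_survival <- function(rate, mean_follow_up) {
  check_positive(rate, "rate")
  check_positive(mean_follow_up, "mean_follow_up")
  e <- rate * mean_follow_up
  if (e >= 1) {
    warning("rate * mean_follow_up >= 1: more than one expected event per ",
            "subject; check the rate and follow-up units", call. = FALSE)
  }
  1 - exp(2 * e * (log(e) - 1))
}

#' Convert an anticipated Nagelkerke R-squared to the Cox-Snell scale
#'
#' The Nagelkerke R-squared rescales the Cox-Snell R-squared by its
#' outcome-dependent maximum so that it spans (0, 1):
#' \eqn{R^2_{N} = R^2_{CS} / \max R^2_{CS}}. Sample-size criteria need
#' the Cox-Snell value, so an anticipated Nagelkerke fit is converted by
#' \eqn{R^2_{CS} = R^2_{N} \cdot \max R^2_{CS}}.
#'
#' @param r2_nagelkerke Anticipated Nagelkerke R-squared, in (0, 1).
#' @param max_r2_cs Ceiling of the Cox-Snell R-squared for the outcome,
#'   from [max_r2cs_binary()] or [max_r2cs_survival()].
#' @return An object of class `"effect_size_spec"`: a list with elements
#'   `r2_nagelkerke`, `max_r2_cs` and `r2_cs`.
#' @examples
#' nagelkerke_to_cox_snell(0.3, max_r2cs_binary(0.5))  # R2_CS = 0.225
#' @export
nagelkerke_to_cox_snell <- function(r2_nagelkerke, max_r2_cs) {
  check_proportion(r2_nagelkerke, "r2_nagelkerke")
  check_proportion(max_r2_cs, "max_r2_cs")
  structure(
    list(r2_nagelkerke = r2_nagelkerke,
         max_r2_cs = max_r2_cs,
         r2_cs = r2_nagelkerke * max_r2_cs),
    class = "effect_size_spec"
  )
}

#' @rdname nagelkerke_to_cox_snell
#' @param r2_cs A Cox-Snell R-squared, in (0, `max_r2_cs`).
#' @export
cox_snell_to_nagelkerke <- function(r2_cs, max_r2_cs) {
  check_proportion(max_r2_cs, "max_r2_cs")
  if (!is.numeric(r2_cs) || r2_cs <= 0 || r2_cs >= max_r2_cs) {
    stop("`r2_cs` must lie in (0, max_r2_cs)", call. = FALSE)
  }
  structure(
    list(r2_nagelkerke = r2_cs / max_r2_cs,
         max_r2_cs = max_r2_cs,
         r2_cs = r2_cs),
    class = "effect_size_spec"
  )
}

#' @export
print.effect_size_spec <- function(x, ...) {
  cat("Anticipated model fit\n")
  cat(sprintf("  Nagelkerke R2 : %.4f\n", x$r2_nagelkerke))
  cat(sprintf("  max Cox-Snell : %.4f\n", x$max_r2_cs))
  cat(sprintf("  Cox-Snell R2  : %.4f\n", x$r2_cs))
  invisible(x)
}

#' Person-time incidence rate approximated from summary statistics
#'
#' Planning a time-to-event model requires the incidence (person-time)
#' rate: events divided by the total follow-up time contributed by all
#' subjects. When only summary epidemiology is available, the total time
#' is approximated by giving each of the \eqn{pN} events the median
#' time-to-event and each of the \eqn{(1-p)N} non-events the median
#' follow-up time:
#' \deqn{\lambda \approx \frac{p}{p\, t_{event} + (1-p)\, t_{fu}}}
#' with \eqn{p} the outcome proportion. The rate is returned at full
#' precision; round only when reporting.
#'
#' @param prevalence Outcome proportion \eqn{p}, in (0, 1).
#' @param median_time_to_event Median time to the event, in months.
#' @param median_follow_up Median follow-up of non-events, in months.
#'   When the follow-up is unknown but the prevalence refers to a fixed
#'   time point, that time point may be supplied here, treating all
#'   non-events as censored there.
#' @return The approximate incidence rate, in events per person-month.
#' @examples
#' person_time_rate(0.307, 24.2, 60)   # ~0.0063 events/person-month
#' person_time_rate(0.5, 10, 20)       # 5 events over 150 person-months
#' @export
person_time_rate <- function(prevalence, median_time_to_event,
                             median_follow_up) {
  check_proportion(prevalence, "prevalence")
  check_positive(median_time_to_event, "median_time_to_event")
  check_positive(median_follow_up, "median_follow_up")
  prevalence / (prevalence * median_time_to_event +
                  (1 - prevalence) * median_follow_up)
}
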