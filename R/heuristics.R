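#' Events-per-predictor rule-of-thumb sample size
#'
#' The classical rule demands a minimum number of outcome events per
#' candidate predictor parameter — 10 historically, relaxed to 5 for
#' some logistic and Cox settings — giving
#' \eqn{n = \lceil EPP \cdot p / \phi \rceil}. These rules ignore the
#' anticipated model fit and outcome type and are provided for
#' comparison with the multi-criterion sizes, which they can under- or
#' over-shoot substantially. For time-to-event endpoints the event
#' proportion (prevalence) is used, not the person-time rate.
#'
#' @param events_per_predictor Required events per predictor (e.g. 10
#'   or 5).
#' @param n_predictors Number of candidate predictor parameters.
#' @param prevalence Outcome proportion, in (0, 1].
#' @return Integer sample size.
#' @examples
#' epp_rule_n(10, 30, 0.5)  # 600
#' epp_rule_n(5, 30, 0.5)   # 300
#' @export
epp_rule_n <- function(events_per_predictor, n_predictors, prevalence) {
  check_positive(events_per_predictor, "events_per_predictor")
  n_predictors <- check_count(n_predictors, "n_predictors")
  check_proportion(prevalence, "prevalence", open = FALSE)
  as.integer(ceiling(events_per_predictor * n_predictors / prevalence))
}

#' Validation cohort size from a required event count
#'
#' Validating a fixed prediction model is driven by the number of
#' events observed, with 100 events a consensus minimum and 200 a
#' desirable target; the cohort size is the event count divided by the
#' outcome proportion, rounded up.
#'
#' @param prevalence Outcome proportion, in (0, 1].
#' @param events Event counts to convert; the first is reported as the
#'   minimum, the second (if any) as the desirable size. Default
#'   `c(100, 200)`.
#' @return An object of class `"cpm_validation"`: list with
#'   `n_minimum`, `n_desirable`, `sizes` (one per requested event
#'   count) and `prevalence`.
#' @examples
#' validation_size(0.307)  # 326 minimum, 652 desirable
#' @export
validation_size <- function(prevalence, events = c(100, 200)) {
  check_proportion(prevalence, "prevalence", open = FALSE)
  if (!is.numeric(events) || !length(events) || any(events <= 0)) {
    stop("`events` must be positive counts", call. = FALSE)
  }
  sizes <- as.integer(ceiling(events / prevalence))
  names(sizes) <- paste0("events_", events)
  structure(
    list(n_minimum = sizes[[1L]],
         n_desirable = if (length(sizes) >= 2L) sizes[[2L]] else NA_integer_,
         sizes = sizes,
         events = events,
         prevalence = prevalence),
    class = "cpm_validation"
  )
}

#' @export
print.cpm_validation <- function(x, ...) {
  cat(sprintf("Validation cohort size (prevalence %g)\n", x$prevalence))
  for (i in seq_along(x$sizes)) {
    tag <- if (i == 1L) "minimum" else if (i == 2L) "desirable" else "   "
    cat(sprintf("  %-9s (%g events): %d patients\n",
                tag, x$events[i], x$sizes[i]))
  }
  invisible(x)
}

#' @export
as.data.frame.cpm_validation <- function(x, ...) {
  data.frame(prevalence = x$prevalence,
             n_minimum = x$n_minimum,
             n_desirable = x$n_desirable,
             stringsAsFactors = FALSE)
}
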