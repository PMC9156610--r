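# Sensitivity sweeps: how the development size reacts to the predictor
# count, the anticipated fit, and the follow-up/time-point ratio.

new_cpm_sweep <- function(scenario, parameter, grid, results) {
  stopifnot(length(grid) == length(results))
  if (is.unsorted(grid, strictly = TRUE)) {
    stop("sweep grid must be strictly increasing", call. = FALSE)
  }
  structure(
    list(scenario_id = scenario$id,
         label = scenario$label,
         swept_parameter = parameter,
         grid = grid,
         final_n = vapply(results, `[[`, integer(1), "final_n"),
         epp = vapply(results, `[[`, numeric(1), "epp"),
         results = results),
    class = "cpm_sweep"
  )
}

#' Sweep the number of candidate predictors
#'
#' Recomputes the development size of a scenario over a grid of
#' predictor counts, all other parameters held fixed. Because the
#' shrinkage and optimism criteria are exactly proportional to the
#' predictor count (before rounding up), the final size is close to
#' linear in the count whenever one of them dominates; the flat
#' risk-precision criterion takes over at small counts.
#'
#' @param scenario A [prediction_scenario].
#' @param grid Strictly increasing predictor counts; default
#'   `seq(5, 30, by = 5)`.
#' @param ... Passed on to [cpm_size()].
#' @return An object of class `"cpm_sweep"` with aligned `grid`,
#'   `final_n` and `epp` vectors (plus the full per-point results).
#' @examples
#' sweep_predictors(load_scenarios()[["hr_nb_mort5y"]])
#' @export
sweep_predictors <- function(scenario, grid = seq(5L, 30L, by = 5L), ...) {
  results <- lapply(grid, function(p) cpm_size(scenario, n_predictors = p, ...))
  new_cpm_sweep(scenario, "n_predictors", grid, results)
}

#' Sweep the anticipated Nagelkerke R-squared
#'
#' @inheritParams sweep_predictors
#' @param grid Strictly increasing Nagelkerke R-squared values; default
#'   `c(0.15, 0.3, 0.5, 0.8)`.
#' @return A `"cpm_sweep"`.
#' @examples
#' sweep_r2(load_scenarios()[["hr_nb_mort5y"]])
#' @export
sweep_r2 <- function(scenario, grid = c(0.15, 0.3, 0.5, 0.8), ...) {
  results <- lapply(grid, function(r2) cpm_size(scenario, r2_nagelkerke = r2, ...))
  new_cpm_sweep(scenario, "r2_nagelkerke", grid, results)
}

#' Sweep the follow-up / prediction-time-point ratio
#'
#' For time-to-event scenarios, varies the anticipated mean follow-up
#' of the development cohort as `ratio * prediction_timepoint`. Longer
#' follow-up accrues more events per recruited subject, so the required
#' size falls as the ratio grows, with diminishing returns.
#'
#' By default the person-time rate keeps its epidemiological value: the
#' rate describes the disease, while the sweep varies the design of the
#' planned cohort. Set `scale_rate = TRUE` to also scale the median
#' follow-up inside the rate approximation by the same ratio (a
#' different reading in which the source cohorts lengthen too; it
#' yields much weaker reductions).
#'
#' @inheritParams sweep_predictors
#' @param grid Strictly increasing positive ratios; default `1:4`.
#' @param scale_rate Logical; see Details. Default `FALSE`.
#' @return A `"cpm_sweep"`.
#' @examples
#' sweep_followup_ratio(load_scenarios()[["nb_death_tte"]])
#' @export
sweep_followup_ratio <- function(scenario, grid = 1:4, scale_rate = FALSE,
                                 ...) {
  if (!inherits(scenario, "prediction_scenario")) {
    stop("`scenario` must be a prediction_scenario", call. = FALSE)
  }
  if (scenario$outcome_kind != "time_to_event") {
    stop(sprintf("scenario '%s' is binary: the follow-up ratio sweep needs ",
                 scenario$id), "a time_to_event scenario", call. = FALSE)
  }
  if (any(grid <= 0)) stop("ratios must be positive", call. = FALSE)
  base_rate <- person_time_rate(scenario$prevalence,
                                scenario$median_time_to_event,
                                scenario$median_follow_up)
  results <- lapply(grid, function(r) {
    fu <- r * scenario$prediction_timepoint
    rate <- if (scale_rate) {
      person_time_rate(scenario$prevalence, scenario$median_time_to_event,
                       r * scenario$median_follow_up)
    } else {
      base_rate
    }
    res <- develop_survival(scenario$n_predictors, rate,
                            prediction_timepoint = scenario$prediction_timepoint,
                            mean_follow_up = fu,
                            r2_nagelkerke = scenario$r2_nagelkerke,
                            shrinkage_target = scenario$shrinkage_target, ...)
    res$scenario_id <- scenario$id
    res$label <- scenario$label
    res
  })
  new_cpm_sweep(scenario, "followup_ratio", grid, results)
}

#' @export
print.cpm_sweep <- function(x, ...) {
  cat(sprintf("Sample-size sweep over %s for '%s'\n",
              x$swept_parameter, x$label))
  print(as.data.frame(x), row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.cpm_sweep <- function(x, ...) {
  df <- data.frame(scenario_id = x$scenario_id,
                   parameter = x$swept_parameter,
                   value = x$grid,
                   final_n = x$final_n,
                   epp = x$epp,
                   stringsAsFactors = FALSE)
  rownames(df) <- NULL
  df
}

#' Plot a sensitivity sweep
#'
#' Base-graphics line plot of the final development size against the
#' swept parameter.
#'
#' @param x A `"cpm_sweep"`.
#' @param ... Passed to [graphics::plot.default()].
#' @export
plot.cpm_sweep <- function(x, ...) {
  xlab <- switch(x$swept_parameter,
                 n_predictors = "candidate predictor parameters",
                 r2_nagelkerke = "anticipated Nagelkerke R-squared",
                 followup_ratio = "follow-up / time-point ratio",
                 x$swept_parameter)
  graphics::plot(x$grid, x$final_n, type = "b", pch = 16,
                 xlab = xlab, ylab = "minimum sample size",
                 main = x$label, ...)
  invisible(x)
}
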