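#' Define a prediction-model planning scenario
#'
#' A scenario bundles the epidemiological summary of one clinical
#' endpoint with the planning parameters of the model to be developed
#' for it. Binary endpoints need only the outcome prevalence;
#' time-to-event endpoints additionally need the median time-to-event
#' and median follow-up (to approximate the person-time rate), the
#' prediction time point, and the anticipated mean follow-up of the
#' development cohort. All times are in months.
#'
#' @param id Short unique label, e.g. `"nb_mort5y"`.
#' @param outcome_kind `"binary"` or `"time_to_event"`.
#' @param prevalence Outcome proportion by the prediction time point,
#'   in (0, 1).
#' @param label Human-readable endpoint description (defaults to `id`).
#' @param tumour Cohort tag, free text (e.g. `"NB"`, `"HR-NB"`, `"DIPG"`).
#' @param median_time_to_event,median_follow_up,prediction_timepoint,study_follow_up
#'   Months; required for (and only allowed on) time-to-event scenarios.
#' @param n_predictors Number of candidate predictor parameters
#'   (default 30).
#' @param r2_nagelkerke Anticipated Nagelkerke R-squared (default 0.3).
#' @param shrinkage_target Expected uniform shrinkage factor the
#'   development sample must support (default 0.9).
#' @return An object of class `"prediction_scenario"`.
#' @seealso [load_scenarios()] for the bundled registry,
#'   [cpm_size()] to compute development sizes from a scenario.
#' @examples
#' prediction_scenario("ex_bin", "binary", prevalence = 0.4)
#' @export
prediction_scenario <- function(id, outcome_kind, prevalence,
                                label = id, tumour = NA_character_,
                                median_time_to_event = NULL,
                                median_follow_up = NULL,
                                prediction_timepoint = NULL,
                                study_follow_up = NULL,
                                n_predictors = 30,
                                r2_nagelkerke = 0.3,
                                shrinkage_target = 0.9) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id)) {
    stop("scenario `id` must be a non-empty string", call. = FALSE)
  }
  fail <- function(field, msg) {
    stop(sprintf("scenario '%s': field `%s` %s", id, field, msg),
         call. = FALSE)
  }
  outcome_kind <- as.character(outcome_kind)
  if (!outcome_kind %in% c("binary", "time_to_event")) {
    fail("outcome_kind", "must be 'binary' or 'time_to_event'")
  }
  if (!is.numeric(prevalence) || length(prevalence) != 1L ||
      is.na(prevalence) || prevalence <= 0 || prevalence >= 1) {
    fail("prevalence", "must lie in (0, 1)")
  }
  if (!is.numeric(n_predictors) || length(n_predictors) != 1L ||
      is.na(n_predictors) || n_predictors < 1 ||
      n_predictors != as.integer(n_predictors)) {
    fail("n_predictors", "must be a positive whole number")
  }
  if (!is.numeric(r2_nagelkerke) || r2_nagelkerke <= 0 || r2_nagelkerke >= 1) {
    fail("r2_nagelkerke", "must lie in (0, 1)")
  }
  if (!is.numeric(shrinkage_target) || shrinkage_target <= 0 ||
      shrinkage_target >= 1) {
    fail("shrinkage_target", "must lie in (0, 1)")
  }

  times <- list(median_time_to_event = median_time_to_event,
                median_follow_up = median_follow_up,
                prediction_timepoint = prediction_timepoint,
                study_follow_up = study_follow_up)
  given <- !vapply(times, is.null, logical(1))
  if (outcome_kind == "binary") {
    if (any(given)) {
      fail(names(times)[which(given)[1L]],
           "is not allowed on a binary scenario")
    }
    times <- lapply(times, function(x) NA_real_)
  } else {
    if (!all(given)) {
      fail(names(times)[which(!given)[1L]],
           "is required for a time_to_event scenario")
    }
    for (nm in names(times)) {
      v <- times[[nm]]
      if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0) {
        fail(nm, "must be a single positive number of months")
      }
    }
    if (times$median_time_to_event >= times$median_follow_up) {
      warning(sprintf(
        "scenario '%s': median_time_to_event (%g) >= median_follow_up (%g)",
        id, times$median_time_to_event, times$median_follow_up),
        call. = FALSE)
    }
  }

  structure(
    c(list(id = id, label = as.character(label),
           tumour = as.character(tumour), outcome_kind = outcome_kind,
           prevalence = as.numeric(prevalence)),
      lapply(times, as.numeric),
      list(n_predictors = as.integer(n_predictors),
           r2_nagelkerke = as.numeric(r2_nagelkerke),
           shrinkage_target = as.numeric(shrinkage_target))),
    class = "prediction_scenario"
  )
}

#' @export
print.prediction_scenario <- function(x, ...) {
  cat(sprintf("Prediction scenario '%s' (%s)\n", x$id, x$label))
  cat(sprintf("  outcome    : %s, prevalence %.4g\n",
              x$outcome_kind, x$prevalence))
  if (x$outcome_kind == "time_to_event") {
    cat(sprintf("  times (mo) : median event %g, median follow-up %g,\n",
                x$median_time_to_event, x$median_follow_up))
    cat(sprintf("               prediction at %g, cohort follow-up %g\n",
                x$prediction_timepoint, x$study_follow_up))
  }
  cat(sprintf("  planning   : %d predictors, R2_Nagelkerke %g, shrinkage %g\n",
              x$n_predictors, x$r2_nagelkerke, x$shrinkage_target))
  invisible(x)
}

#' @export
as.data.frame.prediction_scenario <- function(x, ...) {
  data.frame(lapply(unclass(x), function(v) if (length(v)) v else NA),
             stringsAsFactors = FALSE)
}

new_scenario_set <- function(scenarios) {
  ids <- vapply(scenarios, `[[`, character(1), "id")
  if (anyDuplicated(ids)) {
    stop("duplicate scenario ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  names(scenarios) <- ids
  structure(scenarios, class = "scenario_set")
}

#' @export
print.scenario_set <- function(x, ...) {
  cat(sprintf("A set of %d prediction scenario(s)\n", length(x)))
  if (length(x)) print(as.data.frame(x)[, c("id", "tumour", "outcome_kind",
                                            "prevalence")], row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.scenario_set <- function(x, ...) {
  do.call(rbind, lapply(unclass(x), as.data.frame))
}

#' @export
`[.scenario_set` <- function(x, i) new_scenario_set(unclass(x)[i])

#' Load the bundled paediatric-oncology scenario registry
#'
#' Returns the eleven planning scenarios of the PRIMAGE case study:
#' clinical endpoints for neuroblastoma (NB), high-risk neuroblastoma
#' (HR-NB) and diffuse intrinsic pontine glioma (DIPG), seven with
#' binary outcomes and four time-to-event. Prevalences are stored at
#' the precision reported in the source epidemiology (e.g. 0.2575 for
#' NB relapse/progression), not at table-rounded precision, because the
#' derived sizes are only reproducible from the former.
#'
#' @return A `"scenario_set"` (named list of
#'   [prediction_scenario] objects).
#' @examples
#' reg <- load_scenarios()
#' reg[["hr_nb_mort5y"]]
#' @export
load_scenarios <- function() {
  path <- system.file("extdata", "primage_scenarios.yaml",
                      package = "cpmsize")
  if (!nzchar(path)) stop("bundled scenario registry not found")
  read_scenarios(path)
}

#' Read or parse scenario definitions
#'
#' Scenario files are YAML or JSON lists of mappings using the field
#' names of [prediction_scenario()]. Unspecified planning fields take
#' the defaults (30 predictors, Nagelkerke R-squared 0.3, shrinkage
#' 0.9). Every entry is validated; errors name the offending scenario
#' and field.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @param text A character scalar holding the document itself.
#' @param format `"yaml"` or `"json"`; inferred from the file extension
#'   by `read_scenarios()`.
#' @return A `"scenario_set"`.
#' @export
read_scenarios <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "yaml"
  }
  parse_scenarios(paste(readLines(path, warn = FALSE), collapse = "\n"),
                  format = format)
}

#' @rdname read_scenarios
#' @export
parse_scenarios <- function(text, format = c("yaml", "json")) {
  format <- match.arg(format)
  entries <- switch(format,
    yaml = yaml::yaml.load(text),
    json = jsonlite::fromJSON(text, simplifyDataFrame = FALSE)
  )
  if (is.null(entries)) entries <- list()
  if (!is.list(entries)) {
    stop("scenario document must be a list of mappings", call. = FALSE)
  }
  new_scenario_set(lapply(entries, function(e) {
    known <- names(formals(prediction_scenario))
    extra <- setdiff(names(e), known)
    if (length(extra)) {
      stop(sprintf("scenario '%s': unknown field(s) %s",
                   if (is.null(e$id)) "<unnamed>" else e$id,
                   paste0("`", extra, "`", collapse = ", ")), call. = FALSE)
    }
    do.call(prediction_scenario, e)
  }))
}

#' Serialize scenarios back to a config document
#'
#' Writes the same schema [read_scenarios()] accepts, so a round trip
#' through `write_scenarios()` and `read_scenarios()` reproduces the
#' set exactly.
#'
#' @param scenarios A `"scenario_set"` or list of scenarios.
#' @param path Output file; when `NULL` the document is returned as a
#'   character scalar.
#' @inheritParams read_scenarios
#' @export
write_scenarios <- function(scenarios, path = NULL,
                            format = c("yaml", "json")) {
  format <- match.arg(format)
  entries <- lapply(unclass(scenarios), function(s) {
    s <- unclass(s)
    s <- s[!vapply(s, function(v) is.na(v) || is.null(v), logical(1))]
    s
  })
  names(entries) <- NULL
  doc <- switch(format,
    yaml = yaml::as.yaml(entries),
    json = jsonlite::toJSON(entries, auto_unbox = TRUE, digits = NA,
                            pretty = TRUE)
  )
  if (is.null(path)) return(doc)
  writeLines(doc, path)
  invisible(path)
}
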