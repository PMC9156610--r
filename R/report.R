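#' Assemble the full planning report for a set of scenarios
#'
#' Computes, for every scenario: the approximated person-time rate
#' (time-to-event scenarios only), the multi-criterion development size
#' with its implied EPP alongside the 10- and 5-EPP rule-of-thumb
#' sizes, a sensitivity table over anticipated Nagelkerke R-squared
#' values, and the events-based validation sizes. Output is fully
#' deterministic: the same input yields byte-identical written files.
#'
#' @param scenarios A `"scenario_set"` (e.g. [load_scenarios()]) or
#'   list of [prediction_scenario] objects.
#' @param r2_grid Nagelkerke R-squared values for the sensitivity
#'   table; default `c(0.15, 0.3, 0.5, 0.8)`.
#' @param validation_events Event counts for the validation table;
#'   default `c(100, 200)`.
#' @param include_timestamp Add a generation timestamp to the metadata
#'   (off by default so repeated runs are byte-identical).
#' @param ... Passed on to [cpm_size()] (e.g. `rate_digits`).
#' @return An object of class `"cpm_report"`: list of data frames
#'   `rates_table`, `development_table`, `r2_sensitivity_table`,
#'   `validation_table`, plus `metadata` and `errors` (per-scenario
#'   failures, as messages; one failing scenario does not abort the
#'   rest).
#' @examples
#' rep <- run_report(load_scenarios())
#' rep$development_table
#' @export
run_report <- function(scenarios, r2_grid = c(0.15, 0.3, 0.5, 0.8),
                       validation_events = c(100, 200),
                       include_timestamp = FALSE, ...) {
  if (inherits(scenarios, "prediction_scenario")) {
    scenarios <- list(scenarios)
  }
  scenarios <- unclass(scenarios)
  if (!length(scenarios)) stop("no scenarios", call. = FALSE)

  rates <- list(); devel <- list(); sens <- list(); valid <- list()
  errors <- character()
  for (s in scenarios) {
    ok <- tryCatch({
      if (s$outcome_kind == "time_to_event") {
        rate <- person_time_rate(s$prevalence, s$median_time_to_event,
                                 s$median_follow_up)
        rates[[s$id]] <- data.frame(
          scenario_id = s$id, label = s$label,
          prevalence = s$prevalence,
          median_time_to_event = s$median_time_to_event,
          median_follow_up = s$median_follow_up,
          rate = rate, stringsAsFactors = FALSE)
      }
      dev <- cpm_size(s, ...)
      devel[[s$id]] <- data.frame(
        scenario_id = s$id, label = s$label,
        final_n = dev$final_n,
        n_10epp = epp_rule_n(10, s$n_predictors, s$prevalence),
        n_5epp = epp_rule_n(5, s$n_predictors, s$prevalence),
        epp = dev$epp, stringsAsFactors = FALSE)
      sw <- lapply(r2_grid, function(r2) cpm_size(s, r2_nagelkerke = r2, ...))
      sens[[s$id]] <- data.frame(
        scenario_id = s$id,
        r2_nagelkerke = r2_grid,
        final_n = vapply(sw, `[[`, integer(1), "final_n"),
        epp = vapply(sw, `[[`, numeric(1), "epp"),
        stringsAsFactors = FALSE)
      v <- validation_size(s$prevalence, validation_events)
      valid[[s$id]] <- data.frame(
        scenario_id = s$id, label = s$label,
        n_minimum = v$n_minimum, n_desirable = v$n_desirable,
        stringsAsFactors = FALSE)
      TRUE
    }, error = function(e) {
      errors[[length(errors) + 1L]] <<-
        sprintf("%s: %s", s$id, conditionMessage(e))
      FALSE
    })
    invisible(ok)
  }

  bind <- function(lst) {
    if (!length(lst)) return(NULL)
    out <- do.call(rbind, unname(lst))
    rownames(out) <- NULL
    out
  }
  metadata <- list(
    package = "cpmsize",
    version = as.character(utils::packageVersion("cpmsize")),
    defaults = list(shrinkage_target = 0.9, optimism_margin = 0.05,
                    risk_margin = 0.05),
    r2_grid = r2_grid,
    validation_events = validation_events
  )
  if (include_timestamp) {
    metadata$generated <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  }
  structure(
    list(rates_table = bind(rates),
         development_table = bind(devel),
         r2_sensitivity_table = bind(sens),
         validation_table = bind(valid),
         metadata = metadata,
         errors = errors),
    class = "cpm_report"
  )
}

#' @export
print.cpm_report <- function(x, ...) {
  cat("Prediction-model sample-size report\n\n")
  for (nm in c("rates_table", "development_table", "validation_table")) {
    if (is.null(x[[nm]])) next
    cat(nm, ":\n", sep = "")
    print(format_report_table(x[[nm]], nm), row.names = FALSE)
    cat("\n")
  }
  if (length(x$errors)) {
    cat("errors:\n"); for (e in x$errors) cat("  ", e, "\n", sep = "")
  }
  invisible(x)
}

# Fixed rendering precision: rates 4 dp, EPP 2 dp, sizes as integers.
format_report_table <- function(df, name) {
  if (is.null(df)) return(df)
  out <- df
  for (col in names(out)) {
    if (col == "rate") {
      out[[col]] <- sprintf("%.4f", df[[col]])
    } else if (col == "epp") {
      out[[col]] <- sprintf("%.2f", df[[col]])
    } else if (col %in% c("final_n", "n_10epp", "n_5epp",
                          "n_minimum", "n_desirable")) {
      out[[col]] <- sprintf("%d", as.integer(df[[col]]))
    } else if (is.numeric(df[[col]])) {
      out[[col]] <- format(df[[col]], trim = TRUE)
    }
  }
  out
}

#' Write a report bundle to disk
#'
#' CSV output writes one file per table
#' (`rates_table.csv`, `development_table.csv`,
#' `r2_sensitivity_table.csv`, `validation_table.csv`) with fixed
#' numeric precision (rates 4 decimals, EPP 2, sizes as integers);
#' JSON output writes a single `report.json` mirroring the bundle's
#' field names.
#'
#' @param report A `"cpm_report"` from [run_report()].
#' @param dir Output directory (created if needed).
#' @param format `"csv"` or `"json"`.
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir, format = c("csv", "json")) {
  format <- match.arg(format)
  if (!inherits(report, "cpm_report")) {
    stop("`report` must come from run_report()", call. = FALSE)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tables <- c("rates_table", "development_table", "r2_sensitivity_table",
              "validation_table")
  paths <- character()
  if (format == "csv") {
    for (nm in tables) {
      if (is.null(report[[nm]])) next
      p <- file.path(dir, paste0(nm, ".csv"))
      utils::write.csv(format_report_table(report[[nm]], nm), p,
                       row.names = FALSE, quote = TRUE, fileEncoding = "UTF-8")
      paths <- c(paths, p)
    }
  } else {
    p <- file.path(dir, "report.json")
    payload <- report[c(tables, "metadata", "errors")]
    payload <- payload[!vapply(payload, is.null, logical(1))]
    jsonlite::write_json(payload, p, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", pretty = TRUE)
    paths <- p
  }
  invisible(paths)
}
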