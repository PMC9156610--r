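# Internal helpers shared across the package.

# Round half away from zero (commercial rounding). base::round() rounds
# half to even, which disagrees with the reporting convention used for
# events-per-predictor values (e.g. 17.375 -> 17.38).
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# z-quantile for 95% two-sided intervals, fixed by convention rather than
# recomputed, so printed sizes are reproducible to the count.
Z975 <- 1.96

check_proportion <- function(x, name, open = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("`%s` must be a single number", name), call. = FALSE)
  }
  ok <- if (open) x > 0 && x < 1 else x > 0 && x <= 1
  if (!ok) {
    stop(sprintf("`%s` must lie in %s, got %g", name,
                 if (open) "(0, 1)" else "(0, 1]", x), call. = FALSE)
  }
  invisible(x)
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0) {
    stop(sprintf("`%s` must be a single positive number", name), call. = FALSE)
  }
  invisible(x)
}

check_count <- function(x, name) {
  check_positive(x, name)
  if (x != as.integer(x)) {
    stop(sprintf("`%s` must be a whole number, got %g", name, x),
         call. = FALSE)
  }
  invisible(as.integer(x))
}
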