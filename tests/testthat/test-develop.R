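test_that("binary criteria reproduce the published half-prevalence sizes", {
  res <- develop_binary(30, prevalence = 0.5, r2_nagelkerke = 0.3)
  expect_s3_class(res, "cpm_size")
  expect_identical(res$final_n, 1043L)
  expect_identical(unname(res$criterion_sizes["shrinkage"]), 1043)
  expect_identical(unname(res$criterion_sizes["risk_precision"]), 385)
  expect_equal(res$expected_events, 521.5)
  expect_equal(res$epp, 17.38)
  expect_identical(res$final_n, as.integer(max(res$criterion_sizes)))

  # weaker anticipated fit inflates the shrinkage criterion
  low <- develop_binary(30, prevalence = 0.5, r2_nagelkerke = 0.15)
  expect_identical(low$final_n, 2247L)
  expect_equal(low$epp, 37.45)

  # halving the predictor count halves the dominant criterion
  half <- develop_binary(15, prevalence = 0.5, r2_nagelkerke = 0.3)
  expect_identical(half$final_n, 522L)
})

test_that("binary criteria agree with the implicit-shrinkage oracle", {
  set.seed(3)
  for (i in 1:12) {
    p <- sample(5:40, 1)
    phi <- runif(1, 0.1, 0.9)
    r2n <- runif(1, 0.1, 0.6)
    res <- develop_binary(p, phi, r2n)
    max_r2 <- max_r2cs_binary(phi)
    r2cs <- r2n * max_r2
    expect_identical(
      unname(res$criterion_sizes["shrinkage"]),
      as.numeric(oracle_smallest_n(0.9, p, r2cs)),
      label = sprintf("shrinkage p=%d phi=%.3f r2n=%.3f", p, phi, r2n))
    s2 <- r2cs / (r2cs + 0.05 * max_r2)
    expect_identical(
      unname(res$criterion_sizes["optimism"]),
      as.numeric(oracle_smallest_n(s2, p, r2cs)),
      label = sprintf("optimism p=%d phi=%.3f r2n=%.3f", p, phi, r2n))
  }
})

test_that("development size is symmetric in prevalence", {
  set.seed(5)
  for (phi in runif(10, 0.05, 0.5)) {
    a <- develop_binary(30, phi)
    b <- develop_binary(30, 1 - phi)
    expect_identical(a$criterion_sizes, b$criterion_sizes)
  }
})

test_that("final size falls with anticipated fit and grows with predictors", {
  ns <- vapply(c(0.15, 0.3, 0.5, 0.8), function(r2) {
    develop_binary(30, 0.5, r2)$final_n
  }, integer(1))
  expect_true(all(diff(ns) < 0))

  np <- vapply(c(5L, 10L, 20L, 30L, 60L), function(p) {
    develop_binary(p, 0.307, 0.3)$final_n
  }, integer(1))
  expect_true(all(diff(np) >= 0))
})

test_that("unsatisfiable or invalid effect sizes raise errors", {
  expect_error(develop_binary(30, 0.5, r2_nagelkerke = 0.95,
                              shrinkage_target = 0.5),
               "shrinkage criterion unsatisfiable")
  expect_error(develop_binary(30, 1.5), "prevalence")
  expect_error(develop_binary(0, 0.5), "n_predictors")
  expect_error(develop_binary(30, 0.5, effect = nagelkerke_to_cox_snell(
    0.99, 0.95), shrinkage_target = 0.9), "unsatisfiable")
})

test_that("survival sizes match the pinned synthetic oracle fixture", {
  reg <- load_scenarios()
  fix <- oracle_fixture()
  for (i in seq_len(nrow(fix))) {
    s <- reg[[fix$scenario_id[i]]]
    res <- cpm_size(s)
    expect_identical(res$final_n, fix$final_n[i], label = s$id)
    expect_identical(unname(res$criterion_sizes["shrinkage"]),
                     as.numeric(fix$n_shrinkage[i]), label = s$id)
    expect_identical(unname(res$criterion_sizes["optimism"]),
                     as.numeric(fix$n_optimism[i]), label = s$id)
    expect_identical(unname(res$criterion_sizes["risk_precision"]),
                     as.numeric(fix$n_risk_precision[i]), label = s$id)
  }
})

test_that("survival criteria agree with the scan-based oracle off-registry", {
  cases <- list(c(rate = 0.004, tp = 36, fu = 36),
                c(rate = 0.02, tp = 12, fu = 30),
                c(rate = 0.01, tp = 24, fu = 48))
  for (x in cases) {
    res <- develop_survival(20, x["rate"], x["tp"], x["fu"],
                            r2_nagelkerke = 0.25)
    ora <- oracle_develop_survival(x["rate"], x["tp"], x["fu"],
                                   n_predictors = 20, r2n = 0.25)
    expect_identical(unname(res$criterion_sizes), as.numeric(ora),
                     label = paste(x, collapse = "/"))
  }
})

test_that("a slack risk margin leaves the shrinkage criterion in charge", {
  res <- develop_survival(30, 0.0063, 24, 24, risk_margin = 0.5)
  expect_identical(unname(res$criterion_sizes["risk_precision"]), 1)
  expect_identical(res$final_n,
                   as.integer(res$criterion_sizes["shrinkage"]))
})

test_that("rate rounding mode reproduces table-style inputs", {
  reg <- load_scenarios()
  full <- cpm_size(reg[["nb_death_tte"]])
  rounded <- cpm_size(reg[["nb_death_tte"]], rate_digits = 4)
  expect_identical(rounded$inputs$rate, 0.0063)
  # the two modes differ by well under 1%
  expect_lt(abs(full$final_n - rounded$final_n) / full$final_n, 0.01)
})

test_that("tiny event counts attach a warning note", {
  # a near-zero rate: even the shrinkage-driven n accrues < 1 event
  expect_warning(res <- develop_survival(1, 1e-7, 10, 10,
                                         r2_nagelkerke = 0.8,
                                         risk_margin = 0.4),
                 "fewer than one expected event")
  expect_lt(res$expected_events, 1)
  expect_length(res$notes, 1L)
})

test_that("epp_from_n applies half-up rounding and is linear in n", {
  expect_identical(epp_from_n(1043, 0.5, 30), 17.38)
  expect_identical(epp_from_n(2247, 0.5, 30), 37.45)
  expect_identical(epp_from_n(2 * 978, 0.307, 30), 2 * epp_from_n(978, 0.307, 30))
  # half-up, not banker's: 0.125 -> 0.13 at 2 dp
  expect_identical(epp_from_n(125, 0.001, 1), 0.13)
})

test_that("cpm_size methods print and tabulate coherently", {
  res <- cpm_size(load_scenarios()[["hr_nb_mort5y"]])
  expect_output(print(res), "final n\\s+: 1043")
  expect_output(print(summary(res)), "Cox-Snell 0\\.2250")
  df <- as.data.frame(res)
  expect_identical(df$final_n, 1043L)
  expect_identical(df$scenario_id, "hr_nb_mort5y")
})
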