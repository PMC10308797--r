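default_skeleton <- c(0.05, 0.12, 0.25, 0.40, 0.55, 0.68)

test_that("CRM posterior matches dense-grid integration on random data", {
  # no data: prior means
  expect_equal(
    posterior_tox_estimates(default_skeleton, 1.34),
    crm_posterior_oracle(default_skeleton, 1.34, integer(0), integer(0)),
    tolerance = 1e-6
  )
  # 50 random 20-patient fixtures
  set.seed(31)
  for (i in 1:50) {
    assignments <- sample(1:6, 20, replace = TRUE)
    dlt <- rbinom(20, 1, 0.3)
    est <- posterior_tox_estimates(default_skeleton, 1.34, assignments, dlt)
    oracle <- crm_posterior_oracle(default_skeleton, 1.34, assignments, dlt)
    expect_lt(max(abs(est - oracle)), 1e-6)
  }
})

test_that("CRM posterior respects model structure", {
  # all patients at dose 1 with DLTs pull the estimate above the skeleton
  est <- posterior_tox_estimates(default_skeleton, 1.34,
                                 assignments = rep(1L, 6), dlt = rep(1L, 6))
  expect_gt(est[1], default_skeleton[1])
  # dose ordering is preserved for any data
  set.seed(32)
  for (i in 1:20) {
    assignments <- sample(1:6, 15, replace = TRUE)
    dlt <- rbinom(15, 1, 0.5)
    est <- posterior_tox_estimates(default_skeleton, 1.34, assignments, dlt)
    expect_true(all(diff(est) > 0))
    expect_true(all(est > 0 & est < 1))
  }
  # adding a DLT never decreases any dose's estimate
  set.seed(33)
  for (j in 1:6) {
    assignments <- sample(1:6, 10, replace = TRUE)
    dlt <- rbinom(10, 1, 0.2)
    before <- posterior_tox_estimates(default_skeleton, 1.34, assignments, dlt)
    after <- posterior_tox_estimates(default_skeleton, 1.34,
                                     c(assignments, j), c(dlt, 1L))
    expect_true(all(after >= before - 1e-10))
  }
})

test_that("next dose targets the estimate closest to the threshold", {
  est <- c(0.05, 0.15, 0.25, 0.40, 0.55, 0.68)
  expect_identical(next_dose(est, 0.25, 3L, 6L, FALSE), 3L)
  # exact ties break toward the lower dose
  expect_identical(next_dose(c(0.2, 0.3), 0.25, 1L, 2L, FALSE), 1L)
  # no-skip clamps a jump to one level above the highest tried dose
  est2 <- c(0.01, 0.02, 0.03, 0.05, 0.24, 0.6)
  expect_identical(next_dose(est2, 0.25, 2L, 2L, TRUE), 3L)
  expect_identical(next_dose(est2, 0.25, 2L, 2L, FALSE), 5L)
})

test_that("CRM trials escalate sensibly under extreme scenarios", {
  design <- crm_design(20)
  # no toxicity anywhere: always select the top dose, never skip levels
  safe <- dose_scenario(tox = rep(0, 6), orr = rep(0.5, 6))
  set.seed(34)
  for (i in 1:10) {
    res <- run_crm_trial(design, safe)
    expect_identical(res$selected_dose, 6L)
    expect_true(all(res$dlt == 0L))
    jumps <- res$assignments - cummax(c(design$start_dose,
                                        res$assignments[-design$n1]))
    expect_true(all(jumps <= 1L))
  }
  # uniformly extreme toxicity: almost always no dose is selected
  toxic <- dose_scenario(tox = rep(0.9, 6), orr = rep(0.5, 6))
  set.seed(35)
  none <- vapply(1:300, function(i) {
    is.na(run_crm_trial(design, toxic)$selected_dose)
  }, TRUE)
  expect_gte(mean(none), 0.95)
})

test_that("CRM trials concentrate selection on truly acceptable doses", {
  # under the default truth, the MTD (highest dose with true toxicity at or
  # below 0.25) is dose 4; selection should concentrate on doses 3 and 4
  set.seed(36)
  sel <- vapply(1:400, function(i) {
    run_crm_trial(crm_design(30), make_default_dose_scenario())$selected_dose
  }, 0L)
  expect_gte(mean(sel %in% c(3L, 4L), na.rm = TRUE), 0.6)
})

test_that("optimal-dose selection maximizes response among acceptable doses", {
  expect_identical(select_optimal_dose(c(0.1, 0.2, 0.3), c(0.2, 0.5, 0.9), 0.25), 2L)
  expect_identical(select_optimal_dose(c(0.3, 0.4), c(0.5, 0.9), 0.25), NA_integer_)
  expect_identical(select_optimal_dose(c(0.1, 0.15, 0.2), c(0.3, 0.6, 0.5), 0.25), 2L)
  # non-monotone truth: OD and MTD rules disagree as intended
  scen <- make_nonmonotone_dose_scenario()
  od <- select_optimal_dose(scen$tox, scen$orr, 0.25)
  mtd <- max(which(scen$tox <= 0.25))
  expect_lt(od, mtd)
  expect_identical(od, which.max(scen$orr))
})
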