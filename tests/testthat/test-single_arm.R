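test_that("critical values agree with exhaustive tail enumeration", {
  expect_identical(critical_value(42, 0.4, 0.05), 23L)
  expect_identical(critical_value(30, 0.4, 0.05), 17L)
  expect_identical(critical_value(1, 0.4, 0.05), 2L) # rejection impossible
  for (n in c(1, 5, 10, 20, 42, 60, 101, 140, 200)) {
    for (p0 in c(0.2, 0.4, 0.5)) {
      for (alpha in c(0.01, 0.05, 0.1)) {
        expect_equal(critical_value(n, p0, alpha),
                     enum_critical_value(n, p0, alpha))
      }
    }
  }
  expect_error(critical_value(10, 1.2, 0.05), "p0")
  expect_error(critical_value(10, 0.4, 0), "alpha")
})

test_that("exact binomial power: frozen values, conservativeness, monotonicity", {
  expect_equal(exact_power(42, 0.4, 0.6, 0.05), 0.8031616, tolerance = 1e-6)
  expect_equal(exact_power(30, 0.4, 0.6, 0.05), 0.7145044, tolerance = 1e-6)
  expect_equal(exact_power(60, 0.4, 0.6, 0.05), 0.9253763, tolerance = 1e-6)
  expect_equal(exact_power(20, 0.4, 0.6, 0.05), 0.4158929, tolerance = 1e-6)
  expect_equal(exact_power(42, 0.4, 0.6, 0.05),
               enum_binom_power(42, 0.4, 0.6, 0.05))
  # size of the exact test never exceeds the nominal level
  for (n in c(5, 20, 42, 80, 140)) {
    for (p0 in c(0.2, 0.4, 0.6)) {
      expect_lte(exact_power(n, p0, p0, 0.05), 0.05)
    }
  }
  # power is non-decreasing in the true response rate
  pw <- vapply(seq(0.41, 0.95, by = 0.02),
               function(p1) exact_power(42, 0.4, p1, 0.05), 0)
  expect_true(all(diff(pw) >= 0))
})

test_that("minimum sample size scans the sawtooth correctly", {
  expect_identical(minimum_sample_size(0.4, 0.6, 0.05, 0.8, 10, 200), 42L)
  # all patients respond: first n whose tail 0.4^n drops to at most 0.05
  expect_identical(minimum_sample_size(0.4, 1.0, 0.05, 0.8, 1, 100), 4L)
  expect_error(minimum_sample_size(0.4, 0.41, 0.05, 0.99, 10, 20),
               "unachievable")
  # returned n truly is the smallest qualifying one
  n_star <- minimum_sample_size(0.4, 0.6, 0.05, 0.8, 10, 200)
  below <- vapply(10:(n_star - 1), function(n) exact_power(n, 0.4, 0.6, 0.05), 0)
  expect_true(all(below < 0.8))
})

test_that("single-arm trial simulation matches its analytic description", {
  d <- single_arm_design(30, 0.4, 0.6, 0.05)
  set.seed(11)
  res1 <- run_single_arm_trial(d, true_orr = 1.0)
  expect_identical(res1$responses, 30L)
  expect_true(res1$reject)
  res0 <- run_single_arm_trial(d, true_orr = 0.0)
  expect_identical(res0$responses, 0L)
  expect_false(res0$reject)
  # rejection indicator is exactly (responses >= critical value)
  r <- critical_value(d$n2, d$orr0, d$alpha)
  set.seed(12)
  for (i in 1:200) {
    res <- run_single_arm_trial(d, 0.55)
    expect_identical(res$reject, res$responses >= r)
    expect_identical(res$orr_hat, res$responses / d$n2)
  }
  # empirical rejection frequency matches exact power within 3 MC SEs
  set.seed(13)
  hits <- vapply(1:10000, function(i) run_single_arm_trial(d, 0.6)$reject, TRUE)
  pw <- exact_power(30, 0.4, 0.6, 0.05)
  expect_lt(abs(mean(hits) - pw), 3 * sqrt(pw * (1 - pw) / 10000))
})

test_that("design constructor enforces its invariants", {
  expect_error(single_arm_design(0), "n2")
  expect_error(single_arm_design(20, orr0 = 0.6, orr1_alt = 0.5), "exceed")
  expect_error(single_arm_design(20, alpha = 1), "alpha")
})
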