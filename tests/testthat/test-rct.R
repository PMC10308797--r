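test_that("one-sided Fisher p-values equal conditional enumeration", {
  expect_equal(fisher_one_sided_pvalue(0, 5, 0, 5), 1.0)
  expect_equal(fisher_one_sided_pvalue(5, 5, 0, 5), 1 / choose(10, 5))
  # exhaustive check against enumeration and stats::fisher.test for
  # margins up to 30
  for (n1 in c(3, 8, 15)) {
    for (n0 in c(3, 8, 15)) {
      for (x1 in 0:n1) {
        for (x0 in unique(c(0, 1, n0 %/% 2, n0))) {
          p <- fisher_one_sided_pvalue(x1, n1, x0, n0)
          expect_equal(p, enum_fisher_p(x1, n1, x0, n0), tolerance = 1e-12)
          ft <- fisher.test(matrix(c(x1, n1 - x1, x0, n0 - x0), 2),
                            alternative = "greater")$p.value
          expect_equal(p, ft, tolerance = 1e-9)
        }
      }
    }
  }
  # wrong-direction tables are never nominally significant
  for (n in c(4, 9)) {
    for (x0 in 0:n) {
      for (x1 in 0:x0) {
        expect_gte(fisher_one_sided_pvalue(x1, n, x0, n), 0.5)
      }
    }
  }
})

test_that("exact unconditional power matches brute-force enumeration", {
  expect_equal(exact_unconditional_power(5, 0.9, 0.1, 0.05), 0.73609893,
               tolerance = 1e-7)
  expect_equal(exact_unconditional_power(5, 0.9, 0.1, 0.05),
               enum_fisher_power(5, 0.9, 0.1, 0.05), tolerance = 1e-12)
  expect_equal(exact_unconditional_power(8, 0.7, 0.3, 0.1),
               enum_fisher_power(8, 0.7, 0.3, 0.1), tolerance = 1e-12)
  # validity: size never exceeds alpha
  for (n in c(5, 25, 60, 116, 200)) {
    expect_lte(exact_unconditional_power(n, 0.4, 0.4, 0.05), 0.05)
  }
  # power grows with n up to the exact-test sawtooth: single-patient drops
  # of up to ~5 points occur where the discrete rejection region shifts, but
  # the trend over every 10-patient step is strictly increasing
  pw <- vapply(10:200, function(n) exact_unconditional_power(n, 0.6, 0.4, 0.05), 0)
  expect_true(all(diff(pw) > -0.05))
  expect_true(all(diff(pw[seq(1, 191, by = 10)]) > 0))
})

test_that("phase III sizing: frozen value, cap, monotonicity, precondition", {
  expect_identical(phase3_sample_size(0.6, 0.4)$n_per_arm, 116L)
  expect_gte(phase3_sample_size(0.6, 0.4)$power, 0.9)
  # the returned size is the smallest one reaching the target
  expect_lt(exact_unconditional_power(115, 0.6, 0.4, 0.05), 0.9)
  capped <- phase3_sample_size(0.45, 0.4)
  expect_true(capped$capped)
  expect_identical(capped$n_per_arm, 200L)
  huge <- phase3_sample_size(0.99, 0.4)
  expect_false(huge$capped)
  expect_lt(huge$n_per_arm, 20L)
  # larger observed effects never require larger trials (up to the cap)
  ns <- vapply(seq(0.5, 0.9, by = 0.05),
               function(p) phase3_sample_size(p, 0.4)$n_per_arm, 0L)
  expect_true(all(diff(ns) <= 0))
  expect_error(phase3_sample_size(0.4, 0.4), "exceed")
  # normal-approximation switch: close to, but not above, the exact size
  nn <- phase3_sample_size(0.6, 0.4, method = "normal")
  expect_false(nn$capped)
  expect_lte(nn$n_per_arm, 116L)
  # memoization returns identical results
  cache <- new.env()
  a <- phase3_sample_size(0.6, 0.4, cache = cache)
  b <- phase3_sample_size(0.6, 0.4, cache = cache)
  expect_identical(a, b)
})

test_that("RCT simulation is valid and matches exact power", {
  set.seed(21)
  expect_true(run_rct(10, 1, 0, 0.05)$reject)
  # null validity
  set.seed(22)
  rej <- vapply(1:10000, function(i) run_rct(40, 0.4, 0.4, 0.05)$reject, TRUE)
  expect_lte(mean(rej), 0.05 + 3 * sqrt(0.05 * 0.95 / 10000))
  # rejection rate at (0.6, 0.4) matches exact unconditional power
  set.seed(23)
  rej <- vapply(1:10000, function(i) run_rct(105, 0.6, 0.4, 0.05)$reject, TRUE)
  pw <- exact_unconditional_power(105, 0.6, 0.4, 0.05)
  expect_lt(abs(mean(rej) - pw), 3 * sqrt(pw * (1 - pw) / 10000))
  # reject flag is exactly (p_value <= alpha)
  set.seed(24)
  for (i in 1:100) {
    r <- run_rct(20, 0.5, 0.4, 0.05)
    expect_identical(r$reject, r$p_value <= 0.05)
  }
})
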