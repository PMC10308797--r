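test_that("gating: a positive segment implies a positive, continued first trial", {
  segs <- list(
    ddp_segment_A(single_arm_design(30)),
    ddp_segment_B(crm_design(12)),
    ddp_segment_C(enrichment_design(40))
  )
  for (seg in segs) {
    df <- simulate_segment_replicates(seg, n_reps = 200, seed = 61)
    expect_true(all(!df$positive | df$continued))
    expect_true(all(!df$continued | df$phase_a_positive))
    first_n <- switch(seg$type, A = 30, B = 12, C = 40)
    expect_true(all(df$n_total >= first_n))
    expect_true(all(df$n_total <= first_n + 400))
    expect_true(all(df$duration_months > 0))
  }
})

test_that("selection distributions are proper probability distributions", {
  for (seg in list(ddp_segment_B(crm_design(12)),
                   ddp_segment_C(enrichment_design(40)))) {
    m <- estimate_operating_characteristics(seg, n_reps = 150, seed = 62)
    expect_lt(abs(sum(m$selection_distribution) - 1), 1e-12)
    expect_true(all(m$selection_distribution >= 0))
  }
})

test_that("identical seeds give bit-identical results; blocks pool exactly", {
  seg <- ddp_segment_A(single_arm_design(30))
  m1 <- estimate_operating_characteristics(seg, n_reps = 300, seed = 63)
  m2 <- estimate_operating_characteristics(seg, n_reps = 300, seed = 63)
  expect_identical(m1, m2)
  # splitting a run into two consecutive blocks reproduces it exactly
  full <- simulate_segment_replicates(seg, n_reps = 100, seed = 64)
  half1 <- simulate_segment_replicates(seg, n_reps = 50, seed = 64, first_rep = 1)
  half2 <- simulate_segment_replicates(seg, n_reps = 50, seed = 64, first_rep = 51)
  expect_identical(full, rbind(half1, half2))
})

test_that("any rejecting phase II yields an estimate above the historical rate", {
  # precondition guarding the phase III sizing call
  for (n2 in 20:140) {
    expect_gt(critical_value(n2, 0.4, 0.05) / n2, 0.4)
  }
})

test_that("segment A simulation agrees with its semi-analytic decomposition", {
  n2 <- 30
  seg <- ddp_segment_A(single_arm_design(n2))
  m <- estimate_operating_characteristics(seg, n_reps = 4000, seed = 65)
  # independent route: sum over phase II outcomes of binomial mass times
  # exact phase III power at the data-driven size; no phase III simulation
  r <- critical_value(n2, 0.4, 0.05)
  x <- r:n2
  w <- dbinom(x, n2, 0.6)
  cache <- new.env()
  ddp <- sum(w * vapply(x / n2, function(p) {
    n3 <- phase3_sample_size(p, 0.4, cache = cache)$n_per_arm
    exact_unconditional_power(n3, 0.6, 0.4, 0.05)
  }, 0))
  expect_lt(abs(m$ddp_power - ddp), 3 * sqrt(ddp * (1 - ddp) / 4000))
  # enrollment decomposes the same way
  etot <- n2 + sum(w * vapply(x / n2, function(p) {
    2 * phase3_sample_size(p, 0.4, cache = cache)$n_per_arm
  }, 0))
  expect_lt(abs(m$expected_n_total - etot), 4 * m$expected_n_total_se)
})

test_that("segment B phase II positivity matches its closed form", {
  # uniform truth across doses makes the phase II outcome independent of the
  # selected dose: P(positive phase II) = exact binomial power times the
  # binomial probability of passing the toxicity monitor
  scen <- dose_scenario(tox = rep(0.12, 6), orr = rep(0.6, 6))
  seg <- ddp_segment_B(crm_design(10), scenario = scen)
  df <- simulate_segment_replicates(seg, n_reps = 1000, seed = 66)
  cont <- df[df$continued, ]
  expect_gt(nrow(cont), 900)
  p_expect <- exact_power(42, 0.4, 0.6, 0.05) *
    pbinom(floor(0.25 * 42), 42, 0.12)
  p_obs <- mean(cont$phase_b_positive)
  expect_lt(abs(p_obs - p_expect),
            3 * sqrt(p_expect * (1 - p_expect) / nrow(cont)))
})

test_that("segment B exposure metric is zero when every dose is good", {
  scen <- dose_scenario(tox = rep(0.05, 6), orr = rep(0.6, 6))
  seg <- ddp_segment_B(crm_design(10), scenario = scen)
  m <- estimate_operating_characteristics(seg, n_reps = 100, seed = 67)
  expect_identical(m$prob_unsafe_or_ineffective, 0)
})

test_that("segment B counts exposure to unsafe or ineffective doses", {
  scen <- make_default_dose_scenario() # doses 1,2,5,6 are bad
  seg <- ddp_segment_B(crm_design(15), scenario = scen)
  df <- simulate_segment_replicates(seg, n_reps = 100, seed = 68)
  expect_true(all(df$n_unsafe_or_ineffective >= 0))
  expect_true(all(df$n_unsafe_or_ineffective <= df$n_total))
  # a replicate whose phase II ran at a good dose exposes at most n1 patients
  good_sel <- df$selected %in% c("3", "4")
  expect_true(all(df$n_unsafe_or_ineffective[good_sel] <= 15))
})

test_that("sweeping the first-trial size produces coherent curves", {
  seg <- ddp_segment_A(single_arm_design(30))
  sw <- sweep_segment(seg, sizes = c(30, 60), n_reps = 400, seed = 69)
  expect_identical(nrow(sw), 2L)
  expect_true(all(c("ddp_power", "expected_n_total", "expected_duration")
                  %in% names(sw)))
  # more phase II patients: more power and more enrollment
  expect_gt(sw$ddp_power[2], sw$ddp_power[1])
  expect_gt(sw$expected_n_total[2], sw$expected_n_total[1])
  # DDP power can never exceed the first-trial rejection rate
  expect_lte(sw$ddp_power[1], exact_power(30, 0.4, 0.6, 0.05) + 2 * sw$ddp_power_se[1])
})
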