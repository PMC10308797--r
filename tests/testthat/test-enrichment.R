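test_that("stage sizes follow the 50/25/25 rounding rule and sum to n2", {
  expect_identical(stage_sizes(40), c(20L, 10L, 10L))
  expect_identical(stage_sizes(140), c(70L, 35L, 35L))
  expect_identical(stage_sizes(30), c(15L, 8L, 7L))
  for (n2 in 4:60) {
    s <- stage_sizes(n2)
    expect_identical(sum(s), n2)
    expect_true(all(s >= 0L))
  }
})

test_that("one-sided exact McNemar p-values match the sign-test tail", {
  expect_equal(mcnemar_one_sided(10, 0), 0.5^10)
  expect_equal(mcnemar_one_sided(0, 0), 1.0)
  for (b in 0:8) {
    for (cc in 0:8) {
      p <- mcnemar_one_sided(b, cc)
      if (b == cc && b > 0) expect_gte(p, 0.5)
      if (b + cc > 0) {
        # independent oracle: exact binomial test of the discordant split
        bt <- binom.test(b, b + cc, 0.5, alternative = "greater")$p.value
        expect_equal(p, bt, tolerance = 1e-12)
      }
    }
  }
})

make_pairs <- function(bm_exp, bm_ctl, y_exp, y_ctl) {
  data.frame(bm_exp = bm_exp, bm_ctl = bm_ctl, y_exp = y_exp, y_ctl = y_ctl)
}

test_that("interim cutoff update maximizes the subgroup effect", {
  grid <- seq(0.1, 0.9, by = 0.1)
  # identical responses across arms: nothing improves, cutoff retained
  flat <- make_pairs(runif(20), runif(20), rep(1L, 20), rep(1L, 20))
  expect_identical(interim_cutoff_update(flat, grid, 0, 5), 0)
  # hand-built 20-pair fixture: benefit only in pairs above 0.6
  bm <- seq(0.025, 0.975, by = 0.05)
  high <- bm >= 0.6
  fix <- make_pairs(bm, bm, y_exp = as.integer(high), y_ctl = rep(0L, 20))
  expect_equal(interim_cutoff_update(fix, grid, 0, 5), 0.6)
  # unattainable pair minimum: cutoff retained
  expect_identical(interim_cutoff_update(fix, grid, 0, 50), 0)
  # candidates below the current cutoff are never considered
  expect_identical(interim_cutoff_update(fix, grid, 0.7, 5), 0.7)
})

test_that("enrichment trials honor the design contract", {
  # certain-benefit scenario: every pair discordant in one direction
  sure <- biomarker_scenario(orr1_fn = function(x) rep(1, length(x)), orr0 = 0)
  set.seed(41)
  for (i in 1:10) {
    res <- run_enrichment_trial(enrichment_design(40), sure)
    expect_true(res$reject)
    expect_identical(res$n_enrolled, 40L)
    expect_equal(res$orr1_hat_sub, 1)
    expect_equal(res$orr0_hat_sub, 0)
  }
  # cutoff trajectory is monotone non-decreasing and ends at the final value
  design <- enrichment_design(80)
  scen <- make_default_biomarker_scenario()
  set.seed(42)
  for (i in 1:200) {
    res <- run_enrichment_trial(design, scen)
    traj <- c(0, res$cutoff_trajectory)
    expect_true(all(diff(traj) >= 0))
    if (res$reject) {
      expect_identical(res$final_cutoff, traj[length(traj)])
      expect_gt(res$orr1_hat_sub, res$orr0_hat_sub) # guaranteed by rejection
    } else {
      expect_true(is.na(res$final_cutoff))
    }
  }
  # reproducibility: identical seed, identical result
  set.seed(43); a <- run_enrichment_trial(design, scen)
  set.seed(43); b <- run_enrichment_trial(design, scen)
  expect_identical(a, b)
})

test_that("enrichment trial type I error is controlled under the null", {
  null_scen <- make_null_biomarker_scenario(0.4)
  design <- enrichment_design(60)
  set.seed(44)
  rej <- vapply(1:2000, function(i) run_enrichment_trial(design, null_scen)$reject, TRUE)
  expect_lte(mean(rej), 0.05 + 3 * sqrt(0.05 * 0.95 / 2000))
})
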