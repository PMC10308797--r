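#' Phase II adaptive biomarker-enrichment RCT design
#'
#' A randomized phase II trial over a continuous biomarker in `[0,1]`.
#' Patients accrue in three stages (default 50% / 25% / 25% of `n2`) with an
#' interim analysis after each of the first two. At each interim the
#' eligibility cutoff may move up to a candidate grid value that maximizes
#' the estimated treatment effect in the above-cutoff subgroup (never down:
#' enrichment is monotone). Patients are randomized 1:1 within consecutive
#' enrollment pairs, and the final analysis applies a one-sided exact
#' McNemar (sign) test to all complete pairs whose both members meet the
#' final cutoff.
#'
#' @param n2 total patients (>= 4).
#' @param cutoffs candidate cutoff grid, strictly increasing within (0,1).
#' @param stage_fractions accrual fractions of the three stages; must sum
#'   to 1.
#' @param alpha one-sided level of the final McNemar test.
#' @param min_subgroup_pairs minimum complete pairs above a candidate cutoff
#'   for it to be selectable at an interim.
#' @return An object of class `enrichment_design`.
#' @export
enrichment_design <- function(n2, cutoffs = seq(0.1, 0.9, by = 0.1),
                              stage_fractions = c(0.5, 0.25, 0.25),
                              alpha = 0.05, min_subgroup_pairs = 5L) {
  n2 <- check_count(n2, "n2", min = 4L)
  if (!is.numeric(cutoffs) || any(cutoffs <= 0) || any(cutoffs >= 1) ||
      any(diff(cutoffs) <= 0)) {
    stop("'cutoffs' must be strictly increasing within (0,1)", call. = FALSE)
  }
  if (length(stage_fractions) != 3L || any(stage_fractions < 0) ||
      abs(sum(stage_fractions) - 1) > 1e-9) {
    stop("'stage_fractions' must be three non-negative numbers summing to 1",
         call. = FALSE)
  }
  check_prob(alpha, "alpha", lower_open = TRUE, upper_open = TRUE)
  min_subgroup_pairs <- check_count(min_subgroup_pairs, "min_subgroup_pairs",
                                    min = 1L)
  structure(
    list(n2 = n2, cutoffs = as.numeric(cutoffs),
         stage_fractions = as.numeric(stage_fractions), alpha = alpha,
         min_subgroup_pairs = min_subgroup_pairs),
    class = "enrichment_design"
  )
}

#' Stage sizes of the three accrual periods
#'
#' `s1 = round(n2 * f1)`, `s2 = round(n2 * f2)`, `s3 = n2 - s1 - s2`, so the
#' three stages always sum to `n2`.
#'
#' @param n2 total patients.
#' @param stage_fractions accrual fractions summing to 1.
#' @return Integer vector of three stage sizes.
#' @examples
#' stage_sizes(30) # 15 8 7
#' @export
stage_sizes <- function(n2, stage_fractions = c(0.5, 0.25, 0.25)) {
  n2 <- check_count(n2, "n2", min = 4L)
  s1 <- as.integer(round(n2 * stage_fractions[1]))
  s2 <- as.integer(round(n2 * stage_fractions[2]))
  s3 <- n2 - s1 - s2
  if (s3 < 0L) stop("stage fractions produce a negative stage", call. = FALSE)
  c(s1, s2, s3)
}

#' One-sided exact McNemar (sign) test p-value
#'
#' For paired binary outcomes, only discordant pairs are informative:
#' `b` pairs favor the experimental arm, `c` the control arm. Under the null
#' the discordances are symmetric, so the one-sided p-value is the exact
#' binomial tail `P(X >= b | X ~ Binomial(b + c, 1/2))`, and 1 when there are
#' no discordant pairs.
#'
#' @param b discordant pairs in which only the experimental member responded.
#' @param c discordant pairs in which only the control member responded.
#' @return p-value in (0, 1].
#' @examples
#' mcnemar_one_sided(10, 0) # 2^-10
#' @export
mcnemar_one_sided <- function(b, c) {
  b <- check_count(b, "b", min = 0L)
  c <- check_count(c, "c", min = 0L)
  if (b + c == 0L) return(1)
  pbinom(b - 1, b + c, 0.5, lower.tail = FALSE)
}

# estimated ORR difference (experimental - control) among complete pairs
# whose both members have biomarker >= cut; NA when no such pair
subgroup_diff <- function(pairs, cut) {
  sel <- pairs$bm_exp >= cut & pairs$bm_ctl >= cut
  if (!any(sel)) return(NA_real_)
  mean(pairs$y_exp[sel]) - mean(pairs$y_ctl[sel])
}

#' Interim eligibility-cutoff update
#'
#' Among candidate grid cutoffs at or above the current one that retain at
#' least `min_subgroup_pairs` complete pairs (both members at or above the
#' candidate), returns the cutoff maximizing the estimated response-rate
#' difference (experimental minus control) in the above-cutoff subgroup.
#' Ties break toward the lower cutoff (the larger population). The current
#' cutoff is retained when no candidate qualifies or none strictly improves
#' on the estimated difference at the current cutoff.
#'
#' @param pairs data frame of complete pairs with columns `bm_exp`, `bm_ctl`
#'   (biomarkers) and `y_exp`, `y_ctl` (binary responses).
#' @param cutoffs candidate grid.
#' @param current_cutoff eligibility cutoff in force (0 means no
#'   enrichment).
#' @param min_subgroup_pairs minimum qualifying pair count.
#' @return The updated cutoff (never below `current_cutoff`).
#' @export
interim_cutoff_update <- function(pairs, cutoffs, current_cutoff,
                                  min_subgroup_pairs = 5L) {
  cand <- cutoffs[cutoffs >= current_cutoff]
  if (length(cand) == 0L || nrow(pairs) == 0L) return(current_cutoff)
  n_above <- vapply(cand, function(ct) {
    sum(pairs$bm_exp >= ct & pairs$bm_ctl >= ct)
  }, 0L)
  ok <- n_above >= min_subgroup_pairs
  if (!any(ok)) return(current_cutoff)
  cur_diff <- subgroup_diff(pairs, current_cutoff)
  if (is.na(cur_diff)) cur_diff <- -Inf
  diffs <- vapply(cand[ok], function(ct) subgroup_diff(pairs, ct), 0)
  best <- max(diffs)
  if (best <= cur_diff + 1e-12) return(current_cutoff)
  cand[ok][which(diffs >= best - 1e-12)[1L]]
}

#' Simulate one adaptive enrichment trial
#'
#' Stage 1 enrolls from the scenario's full biomarker range; after stages 1
#' and 2 the eligibility cutoff is updated by [interim_cutoff_update()]
#' (monotone non-decreasing), and later stages enroll only patients with
#' biomarker at or above the current cutoff. Within each stage consecutive
#' patients form randomized pairs (one experimental, one control); an odd
#' stage size leaves one unpaired patient who counts toward enrollment but
#' contributes no paired information. The final analysis applies the exact
#' one-sided McNemar test to all complete pairs whose both members meet the
#' cutoff in force at trial end.
#'
#' @param design an [enrichment_design()].
#' @param scenario a [biomarker_scenario()].
#' @return An object of class `enrichment_result`: list with `final_cutoff`
#'   (eligibility cutoff at trial end when the test rejects, `NA` otherwise;
#'   0 means a positive trial without enrichment), `reject`, `orr1_hat_sub`,
#'   `orr0_hat_sub` (response-rate estimates among analyzed pairs),
#'   `n_enrolled`, `pairs_analyzed`, and `cutoff_trajectory` (the cutoff
#'   after each interim).
#' @examples
#' set.seed(1)
#' run_enrichment_trial(enrichment_design(60), make_default_biomarker_scenario())
#' @export
run_enrichment_trial <- function(design, scenario) {
  stopifnot(inherits(design, "enrichment_design"),
            inherits(scenario, "biomarker_scenario"))
  sizes <- stage_sizes(design$n2, design$stage_fractions)
  cutoff <- 0
  trajectory <- numeric(0)
  pairs <- data.frame(bm_exp = numeric(0), bm_ctl = numeric(0),
                      y_exp = integer(0), y_ctl = integer(0))
  for (stage in 1:3) {
    m <- sizes[stage]
    lower <- max(cutoff, scenario$biomarker_lower)
    npair <- m %/% 2L
    if (npair > 0L) {
      bm_exp <- sample_biomarker(lower, npair)
      bm_ctl <- sample_biomarker(lower, npair)
      y_exp <- rbinom(npair, 1L, scenario$orr1_fn(bm_exp))
      y_ctl <- rbinom(npair, 1L, scenario$orr0)
      pairs <- rbind(pairs, data.frame(bm_exp = bm_exp, bm_ctl = bm_ctl,
                                       y_exp = y_exp, y_ctl = y_ctl))
    }
    if (m %% 2L == 1L) {
      # unpaired trailing patient: enrolled (advance the RNG consistently)
      # but contributes no paired information
      bm <- sample_biomarker(lower, 1L)
      rbinom(1L, 1L, if (runif(1) < 0.5) scenario$orr1_fn(bm) else scenario$orr0)
    }
    if (stage < 3L) {
      cutoff <- interim_cutoff_update(pairs, design$cutoffs, cutoff,
                                      design$min_subgroup_pairs)
      trajectory <- c(trajectory, cutoff)
    }
  }
  sel <- pairs$bm_exp >= cutoff & pairs$bm_ctl >= cutoff
  b <- sum(pairs$y_exp[sel] == 1L & pairs$y_ctl[sel] == 0L)
  cc <- sum(pairs$y_exp[sel] == 0L & pairs$y_ctl[sel] == 1L)
  p <- mcnemar_one_sided(b, cc)
  reject <- p <= design$alpha
  structure(
    list(
      final_cutoff = if (reject) cutoff else NA_real_,
      reject = reject,
      p_value = p,
      orr1_hat_sub = if (any(sel)) mean(pairs$y_exp[sel]) else NA_real_,
      orr0_hat_sub = if (any(sel)) mean(pairs$y_ctl[sel]) else NA_real_,
      n_enrolled = design$n2,
      pairs_analyzed = sum(sel),
      cutoff_trajectory = trajectory
    ),
    class = "enrichment_result"
  )
}
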