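#' Define a DDP segment of two consecutive trials
#'
#' A segment couples a first trial, a go/no-go gate, and a second trial whose
#' design can depend on the first trial's results. `ddp_segment_A()` is the
#' phase II single-arm to phase III RCT segment, `ddp_segment_B()` the phase
#' I CRM to single-arm phase II segment, and `ddp_segment_C()` the phase II
#' adaptive-enrichment to phase III RCT segment.
#'
#' @param phase2 first-trial design ([single_arm_design()] for segment A,
#'   [enrichment_design()] for segment C).
#' @param phase3 [rct_design()] template for the second trial of segments A
#'   and C (sized at run time from first-trial estimates).
#' @param scenario truth scenario: for segment A a list with `orr1`, `orr0`
#'   (see [make_example1_scenario()]); for B a [dose_scenario()]; for C a
#'   [biomarker_scenario()].
#' @param enrollment an [enrollment_model()] used for segment duration.
#' @return An object of class `ddp_segment`.
#' @name ddp_segment
NULL

#' @rdname ddp_segment
#' @export
ddp_segment_A <- function(phase2 = single_arm_design(60),
                          phase3 = rct_design(),
                          scenario = make_example1_scenario(),
                          enrollment = enrollment_model()) {
  stopifnot(inherits(phase2, "single_arm_design"),
            inherits(phase3, "rct_design"),
            is.list(scenario), !is.null(scenario$orr1), !is.null(scenario$orr0))
  structure(
    list(type = "A", phase2 = phase2, phase3 = phase3, scenario = scenario,
         enrollment = enrollment),
    class = "ddp_segment"
  )
}

#' @rdname ddp_segment
#' @param phase1 a [crm_design()] (segment B).
#' @param phase2_n fixed sample size of the segment-B phase II trial,
#'   independent of the selected dose.
#' @param orr0 historical control response rate tested against in the
#'   segment-B phase II trial (also the effectiveness threshold: a dose with
#'   true ORR at or below it is ineffective).
#' @param orr1_alt alternative response rate of the segment-B phase II test.
#' @param alpha one-sided level of the segment-B phase II test.
#' @param tox_monitor_threshold maximum acceptable observed toxicity rate in
#'   the segment-B phase II trial; exceeding it discontinues the DDP even
#'   when efficacy is shown.
#' @export
ddp_segment_B <- function(phase1 = crm_design(20),
                          scenario = make_default_dose_scenario(),
                          phase2_n = 42, orr0 = 0.4, orr1_alt = 0.6,
                          alpha = 0.05, tox_monitor_threshold = 0.25,
                          enrollment = enrollment_model()) {
  stopifnot(inherits(phase1, "crm_design"), inherits(scenario, "dose_scenario"))
  phase2 <- single_arm_design(phase2_n, orr0, orr1_alt, alpha)
  check_prob(tox_monitor_threshold, "tox_monitor_threshold")
  structure(
    list(type = "B", phase1 = phase1, phase2 = phase2, scenario = scenario,
         tox_monitor_threshold = tox_monitor_threshold,
         enrollment = enrollment),
    class = "ddp_segment"
  )
}

#' @rdname ddp_segment
#' @export
ddp_segment_C <- function(phase2 = enrichment_design(60),
                          phase3 = rct_design(),
                          scenario = make_default_biomarker_scenario(),
                          enrollment = enrollment_model()) {
  stopifnot(inherits(phase2, "enrichment_design"),
            inherits(phase3, "rct_design"),
            inherits(scenario, "biomarker_scenario"))
  structure(
    list(type = "C", phase2 = phase2, phase3 = phase3, scenario = scenario,
         enrollment = enrollment),
    class = "ddp_segment"
  )
}

segment_result <- function(segment, positive, phase_a_positive, continued,
                           phase_b_positive = NA, selected = NA_character_,
                           n_total, n_unsafe = NA_real_, duration, phase_b_n = NA_real_,
                           capped = FALSE, extra = list()) {
  c(list(segment = segment, positive = positive,
         phase_a_positive = phase_a_positive, continued = continued,
         phase_b_positive = phase_b_positive, selected = selected,
         n_total = n_total, n_unsafe_or_ineffective = n_unsafe,
         duration_months = duration, phase_b_n = phase_b_n, capped = capped),
    extra)
}

#' Simulate one replicate of segment A (phase II single arm, then phase III)
#'
#' Runs the single-arm phase II trial at the scenario's true experimental
#' ORR. On rejection, the phase III per-arm size is computed by
#' [phase3_sample_size()] from the phase II estimate versus the historical
#' control rate (the design's `orr0`), and the phase III RCT is simulated at
#' the scenario's true ORRs. On non-rejection the segment stops with
#' `n_total` equal to the phase II size.
#'
#' @param phase2 a [single_arm_design()].
#' @param phase3 an [rct_design()] template.
#' @param true_orr1,true_orr0 true response probabilities.
#' @param enrollment an [enrollment_model()].
#' @param cache optional memoization environment for phase III sizing.
#' @return A list describing the replicate (positivity, enrollment,
#'   duration, cap status).
#' @export
run_segment_A <- function(phase2, phase3, true_orr1 = 0.6, true_orr0 = 0.4,
                          enrollment = enrollment_model(), cache = NULL) {
  ph2 <- run_single_arm_trial(phase2, true_orr1)
  if (!ph2$reject) {
    return(segment_result("A", positive = FALSE, phase_a_positive = FALSE,
                          continued = FALSE, n_total = phase2$n2,
                          duration = segment_duration(phase2$n2, NULL, enrollment),
                          extra = list(orr_hat = ph2$orr_hat)))
  }
  sz <- phase3_sample_size(ph2$orr_hat, phase2$orr0, phase3$alpha,
                           phase3$target_power, phase3$max_total,
                           method = phase3$sizing %||% "exact", cache = cache)
  ph3 <- run_rct(sz$n_per_arm, true_orr1, true_orr0, phase3$alpha)
  segment_result("A", positive = ph3$reject, phase_a_positive = TRUE,
                 continued = TRUE, phase_b_positive = ph3$reject,
                 n_total = phase2$n2 + 2L * sz$n_per_arm,
                 duration = segment_duration(phase2$n2, 2L * sz$n_per_arm,
                                             enrollment),
                 phase_b_n = 2L * sz$n_per_arm, capped = sz$capped,
                 extra = list(orr_hat = ph2$orr_hat))
}

#' Simulate one replicate of segment B (phase I CRM, then phase II)
#'
#' Runs the CRM trial; if no dose is selected (lowest dose estimated too
#' toxic) the segment stops. Otherwise the fixed-size phase II trial draws
#' responses and toxicities at the selected dose's true probabilities; it is
#' positive when the exact binomial test rejects and the observed toxicity
#' rate stays at or below the monitor threshold. The segment is positive
#' when, in addition, the selected dose is truly safe and effective (true
#' DLT probability at most the CRM target and true ORR above the reference
#' rate). Patients at unsafe or ineffective doses are counted toward the
#' exposure metric: phase I patients dose by dose, and the whole phase II
#' trial when the selected dose is such a dose.
#'
#' @param segment a [ddp_segment_B()] object.
#' @return A list describing the replicate, including
#'   `positive_no_monitor`, the segment-positivity variant that ignores the
#'   phase II toxicity monitor.
#' @export
run_segment_B <- function(segment) {
  phase1 <- segment$phase1
  phase2 <- segment$phase2
  scen <- segment$scenario
  bad_dose <- scen$tox > phase1$tox_target | scen$orr <= phase2$orr0
  crm <- run_crm_trial(phase1, scen)
  j <- crm$selected_dose
  n_unsafe <- sum(bad_dose[crm$assignments])
  if (is.na(j)) {
    return(segment_result("B", positive = FALSE, phase_a_positive = FALSE,
                          continued = FALSE, selected = "none",
                          n_total = phase1$n1, n_unsafe = n_unsafe,
                          duration = segment_duration(phase1$n1, NULL,
                                                      segment$enrollment),
                          extra = list(positive_no_monitor = FALSE)))
  }
  ph2 <- run_single_arm_trial(phase2, scen$orr[j], scen$tox[j])
  tox_pass <- ph2$toxicities / phase2$n2 <= segment$tox_monitor_threshold
  good <- !bad_dose[j]
  if (bad_dose[j]) n_unsafe <- n_unsafe + phase2$n2
  segment_result("B", positive = good && ph2$reject && tox_pass,
                 phase_a_positive = TRUE, continued = TRUE,
                 phase_b_positive = ph2$reject && tox_pass,
                 selected = as.character(j),
                 n_total = phase1$n1 + phase2$n2, n_unsafe = n_unsafe,
                 duration = segment_duration(phase1$n1, phase2$n2,
                                             segment$enrollment),
                 phase_b_n = phase2$n2,
                 extra = list(positive_no_monitor = good && ph2$reject))
}

#' Simulate one replicate of segment C (enrichment phase II, then phase III)
#'
#' Runs the adaptive enrichment trial; on rejection, the phase III per-arm
#' size targets the design's power at the subgroup estimates reported by the
#' phase II trial (capped), and the phase III RCT enrolls only patients with
#' biomarker at or above the selected cutoff, with responses drawn from the
#' true curves restricted to that subgroup.
#'
#' @param segment a [ddp_segment_C()] object.
#' @param cache optional memoization environment for phase III sizing.
#' @return A list describing the replicate.
#' @export
run_segment_C <- function(segment, cache = NULL) {
  design <- segment$phase2
  phase3 <- segment$phase3
  scen <- segment$scenario
  enr <- run_enrichment_trial(design, scen)
  if (!enr$reject) {
    return(segment_result("C", positive = FALSE, phase_a_positive = FALSE,
                          continued = FALSE, selected = "none",
                          n_total = design$n2,
                          duration = segment_duration(design$n2, NULL,
                                                      segment$enrollment)))
  }
  sz <- phase3_sample_size(enr$orr1_hat_sub, enr$orr0_hat_sub, phase3$alpha,
                           phase3$target_power, phase3$max_total,
                           method = phase3$sizing %||% "exact", cache = cache)
  n3 <- sz$n_per_arm
  bm1 <- sample_biomarker(enr$final_cutoff, n3)
  x1 <- sum(rbinom(n3, 1L, scen$orr1_fn(bm1)))
  x0 <- rbinom(1L, n3, scen$orr0)
  p <- fisher_one_sided_pvalue(x1, n3, x0, n3)
  segment_result("C", positive = p <= phase3$alpha, phase_a_positive = TRUE,
                 continued = TRUE, phase_b_positive = p <= phase3$alpha,
                 selected = fmt_cutoff(enr$final_cutoff),
                 n_total = design$n2 + 2L * n3,
                 duration = segment_duration(design$n2, 2L * n3,
                                             segment$enrollment),
                 phase_b_n = 2L * n3, capped = sz$capped,
                 extra = list(final_cutoff = enr$final_cutoff))
}

run_segment_replicate <- function(segment, cache = NULL) {
  switch(segment$type,
    A = run_segment_A(segment$phase2, segment$phase3,
                      segment$scenario$orr1, segment$scenario$orr0,
                      segment$enrollment, cache),
    B = run_segment_B(segment),
    C = run_segment_C(segment, cache),
    stop("unknown segment type", call. = FALSE)
  )
}

#' Simulate seeded replicates of a DDP segment
#'
#' Replicate `i` (global index `first_rep + i - 1`) runs under its own RNG
#' seed derived from `(seed, index)` by [rep_seed()], so results are
#' independent of execution order: running indices `1:5000` and `5001:10000`
#' in two calls and row-binding the results is identical to one call with
#' `n_reps = 10000`.
#'
#' @param segment a `ddp_segment`.
#' @param n_reps number of replicates.
#' @param seed integer base seed.
#' @param first_rep global index of the first replicate.
#' @return A data frame with one row per replicate: positivity indicators,
#'   selection, enrollment, exposure, duration, cap status.
#' @export
simulate_segment_replicates <- function(segment, n_reps, seed = 1L,
                                        first_rep = 1L) {
  stopifnot(inherits(segment, "ddp_segment"))
  n_reps <- check_count(n_reps, "n_reps")
  first_rep <- check_count(first_rep, "first_rep")
  cache <- new.env(parent = emptyenv())
  out <- list(
    rep = integer(n_reps), positive = logical(n_reps),
    phase_a_positive = logical(n_reps), continued = logical(n_reps),
    phase_b_positive = logical(n_reps), selected = character(n_reps),
    n_total = numeric(n_reps), n_unsafe_or_ineffective = numeric(n_reps),
    duration_months = numeric(n_reps), phase_b_n = numeric(n_reps),
    capped = logical(n_reps), positive_no_monitor = logical(n_reps)
  )
  for (i in seq_len(n_reps)) {
    idx <- first_rep + i - 1L
    set.seed(rep_seed(seed, idx))
    r <- run_segment_replicate(segment, cache)
    out$rep[i] <- idx
    out$positive[i] <- r$positive
    out$phase_a_positive[i] <- r$phase_a_positive
    out$continued[i] <- r$continued
    out$phase_b_positive[i] <- r$phase_b_positive %||% NA
    out$selected[i] <- r$selected
    out$n_total[i] <- r$n_total
    out$n_unsafe_or_ineffective[i] <- r$n_unsafe_or_ineffective
    out$duration_months[i] <- r$duration_months
    out$phase_b_n[i] <- r$phase_b_n
    out$capped[i] <- r$capped
    out$positive_no_monitor[i] <- r$positive_no_monitor %||% NA
  }
  as.data.frame(out, stringsAsFactors = FALSE)
}

fmt_cutoff <- function(x) sprintf("%.3g", x)

selection_levels <- function(segment) {
  switch(segment$type,
    A = NULL,
    B = c(as.character(seq_len(segment$phase1$n_doses)), "none"),
    C = c(vapply(c(0, segment$phase2$cutoffs), fmt_cutoff, ""), "none")
  )
}

#' Monte-Carlo operating characteristics of a DDP segment
#'
#' Estimates segment-level performance metrics from seeded replicates: the
#' DDP power (probability that the first trial is positive and the triggered
#' second trial is too), expected total enrollment, the probability that an
#' enrolled patient receives an unsafe or ineffective dose (segment B: the
#' mean over replicates of the within-replicate exposed fraction), expected
#' duration, and the distribution of the selected dose or cutoff. Each
#' proportion carries its Monte-Carlo standard error `sqrt(p(1-p)/n_reps)`;
#' means carry `sd/sqrt(n_reps)`. Identical inputs give bit-identical
#' tables.
#'
#' @inheritParams simulate_segment_replicates
#' @return An object of class `ddp_metrics`.
#' @examples
#' seg <- ddp_segment_A(single_arm_design(30))
#' estimate_operating_characteristics(seg, n_reps = 200, seed = 1)
#' @export
estimate_operating_characteristics <- function(segment, n_reps = 10000L,
                                               seed = 1L, first_rep = 1L) {
  df <- simulate_segment_replicates(segment, n_reps, seed, first_rep)
  summarize_segment_replicates(segment, df, seed)
}

# aggregation split out so pooled replicate frames can be summarized too
summarize_segment_replicates <- function(segment, df, seed = NA_integer_) {
  n <- nrow(df)
  p <- mean(df$positive)
  levels <- selection_levels(segment)
  sel <- if (is.null(levels)) NULL else {
    cnt <- table(factor(df$selected, levels = levels))
    setNames(as.numeric(cnt) / n, levels)
  }
  frac_unsafe <- if (all(is.na(df$n_unsafe_or_ineffective))) NULL else {
    df$n_unsafe_or_ineffective / df$n_total
  }
  pnm <- if (all(is.na(df$positive_no_monitor))) NULL else {
    mean(df$positive_no_monitor)
  }
  structure(
    list(
      segment = segment$type,
      ddp_power = p,
      ddp_power_se = prop_se(p, n),
      ddp_power_no_monitor = pnm,
      expected_n_total = mean(df$n_total),
      expected_n_total_se = mean_se(df$n_total),
      prob_unsafe_or_ineffective = if (is.null(frac_unsafe)) NA_real_ else mean(frac_unsafe),
      prob_unsafe_or_ineffective_se = if (is.null(frac_unsafe)) NA_real_ else mean_se(frac_unsafe),
      expected_duration = mean(df$duration_months),
      expected_duration_se = mean_se(df$duration_months),
      prob_capped = mean(df$capped),
      selection_distribution = sel,
      n_reps = n,
      seed = seed
    ),
    class = "ddp_metrics"
  )
}

#' @export
print.ddp_metrics <- function(x, ...) {
  cat(sprintf("DDP segment %s operating characteristics (%d replicates, seed %s)\n",
              x$segment, x$n_reps, format(x$seed)))
  fmt <- function(v, se) {
    if (is.na(se)) sprintf("%.4g", v) else sprintf("%.4g (MC SE %.2g)", v, se)
  }
  cat("  DDP power:                ", fmt(x$ddp_power, x$ddp_power_se), "\n")
  if (!is.null(x$ddp_power_no_monitor)) {
    cat("  DDP power (no tox monitor):", sprintf("%.4g", x$ddp_power_no_monitor), "\n")
  }
  cat("  Expected total enrollment:", fmt(x$expected_n_total, x$expected_n_total_se), "\n")
  if (!is.na(x$prob_unsafe_or_ineffective)) {
    cat("  P(unsafe/ineffective dose):",
        fmt(x$prob_unsafe_or_ineffective, x$prob_unsafe_or_ineffective_se), "\n")
  }
  cat("  Expected duration (months):",
      fmt(x$expected_duration, x$expected_duration_se), "\n")
  if (!is.null(x$selection_distribution)) {
    cat("  Selection distribution:\n")
    print(round(x$selection_distribution, 4))
  }
  invisible(x)
}

set_first_trial_size <- function(segment, value) {
  value <- check_count(value, "value")
  if (segment$type == "A") {
    d <- segment$phase2
    segment$phase2 <- single_arm_design(value, d$orr0, d$orr1_alt, d$alpha)
  } else if (segment$type == "B") {
    d <- segment$phase1
    segment$phase1 <- crm_design(value, d$skeleton, d$tox_target, d$prior_sd,
                                 d$start_dose, d$no_skip)
  } else {
    d <- segment$phase2
    segment$phase2 <- enrichment_design(value, d$cutoffs, d$stage_fractions,
                                        d$alpha, d$min_subgroup_pairs)
  }
  segment
}

#' Sweep a segment's first-trial sample size
#'
#' Re-estimates operating characteristics over a grid of first-trial sizes,
#' producing the power-versus-sample-size and enrollment-versus-sample-size
#' curves of a segment as one table row per grid point (selection
#' distributions expanded into `sel_*` columns).
#'
#' @param segment a `ddp_segment`.
#' @param sizes integer grid of first-trial sample sizes.
#' @param n_reps replicates per grid point.
#' @param seed integer base seed (reused per grid point, so grid points share
#'   common random replicate seeds).
#' @return A data frame, one row per grid point.
#' @export
sweep_segment <- function(segment, sizes, n_reps = 10000L, seed = 1L) {
  rows <- lapply(sizes, function(sz) {
    m <- estimate_operating_characteristics(set_first_trial_size(segment, sz),
                                            n_reps = n_reps, seed = seed)
    metrics_row(m, first_trial_n = sz)
  })
  do.call(rbind, rows)
}

metrics_row <- function(m, first_trial_n = NA_integer_) {
  base <- data.frame(
    segment = m$segment,
    first_trial_n = first_trial_n,
    n_reps = m$n_reps,
    seed = m$seed,
    ddp_power = m$ddp_power,
    ddp_power_se = m$ddp_power_se,
    ddp_power_no_monitor = m$ddp_power_no_monitor %||% NA_real_,
    expected_n_total = m$expected_n_total,
    expected_n_total_se = m$expected_n_total_se,
    prob_unsafe_or_ineffective = m$prob_unsafe_or_ineffective,
    prob_unsafe_or_ineffective_se = m$prob_unsafe_or_ineffective_se,
    expected_duration = m$expected_duration,
    expected_duration_se = m$expected_duration_se,
    prob_capped = m$prob_capped,
    stringsAsFactors = FALSE
  )
  if (!is.null(m$selection_distribution)) {
    sel <- as.data.frame(as.list(m$selection_distribution))
    names(sel) <- paste0("sel_", names(m$selection_distribution))
    base <- cbind(base, sel)
  }
  base
}
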