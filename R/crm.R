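#' Phase I Continual Reassessment Method (CRM) design
#'
#' One-parameter Bayesian CRM with the empiric power model: the toxicity
#' probability at dose `j` is `skeleton[j]^exp(beta)` with a
#' `Normal(0, prior_sd^2)` prior on `beta`. Patients are treated one at a
#' time; after each outcome the posterior is refit and the next patient is
#' assigned the dose whose estimated toxicity is closest to `tox_target`
#' (optionally without skipping untried levels). The trial selects as maximum
#' tolerated dose (MTD) the highest dose with estimated toxicity at or below
#' `tox_target`, or no dose when even the lowest dose is estimated too toxic.
#'
#' @param n1 number of patients.
#' @param skeleton prior guesses of per-dose toxicity probabilities, strictly
#'   increasing in (0,1). The default places the prior MTD at level 3 of six.
#' @param tox_target maximum acceptable toxicity probability (default 0.25,
#'   a common oncology threshold).
#' @param prior_sd standard deviation of the normal prior on the model
#'   parameter (default 1.34, the conventional empiric-model choice).
#' @param start_dose index of the first assigned dose.
#' @param no_skip if `TRUE`, escalation never skips an untried dose level.
#' @return An object of class `crm_design`.
#' @export
crm_design <- function(n1,
                       skeleton = c(0.05, 0.12, 0.25, 0.40, 0.55, 0.68),
                       tox_target = 0.25, prior_sd = 1.34,
                       start_dose = 3L, no_skip = TRUE) {
  n1 <- check_count(n1, "n1")
  check_skeleton(skeleton)
  check_prob(tox_target, "tox_target", lower_open = TRUE, upper_open = TRUE)
  if (!is.numeric(prior_sd) || length(prior_sd) != 1L || prior_sd <= 0) {
    stop("'prior_sd' must be a positive scalar", call. = FALSE)
  }
  start_dose <- check_count(start_dose, "start_dose")
  if (start_dose > length(skeleton)) {
    stop("'start_dose' must be a valid dose index", call. = FALSE)
  }
  structure(
    list(n1 = n1, n_doses = length(skeleton), skeleton = skeleton,
         tox_target = tox_target, prior_sd = prior_sd,
         start_dose = start_dose, no_skip = isTRUE(no_skip)),
    class = "crm_design"
  )
}

check_skeleton <- function(skeleton) {
  if (!is.numeric(skeleton) || length(skeleton) < 1L ||
      any(!is.finite(skeleton)) || any(skeleton <= 0) || any(skeleton >= 1) ||
      any(diff(skeleton) <= 0)) {
    stop("'skeleton' must be strictly increasing with entries in (0,1)",
         call. = FALSE)
  }
  invisible(skeleton)
}

# Quadrature scaffold for the 1-D posterior integral: composite Simpson rule
# on a fixed wide grid of the model parameter. The prior (sd <= ~2) and any
# likelihood from binary data keep the posterior mass well inside [-12, 12];
# the per-dose toxicity curves over the grid are precomputed so a model refit
# is a handful of vectorized operations.
crm_quadrature <- function(skeleton, prior_sd, n_nodes = 2401L) {
  b <- seq(-12, 12, length.out = n_nodes)
  h <- b[2] - b[1]
  w <- rep(c(2, 4), length.out = n_nodes)
  w[1] <- w[n_nodes] <- 1
  w <- w * h / 3
  logP <- outer(log(skeleton), exp(b)) # J x K matrix of log p_j(beta_k)
  P <- exp(logP)
  list(b = b, prior_w = w * dnorm(b, 0, prior_sd),
       logP = logP, log1mP = log1p(-P), P = P)
}

# posterior-mean toxicity per dose from per-dose DLT / non-DLT counts
posterior_from_counts <- function(quad, n_dlt, n_nodlt) {
  ll <- as.vector(crossprod(quad$logP, n_dlt)) +
    as.vector(crossprod(quad$log1mP, n_nodlt))
  w <- exp(ll - max(ll)) * quad$prior_w
  z <- sum(w)
  if (!is.finite(z) || z <= 0) {
    stop(sprintf(
      "CRM posterior integration failed (normalizing mass %g; %d DLTs, %d non-DLTs)",
      z, sum(n_dlt), sum(n_nodlt)
    ), call. = FALSE)
  }
  as.vector(quad$P %*% w) / z
}

#' Posterior toxicity estimates under the empiric CRM model
#'
#' Posterior mean of the per-dose toxicity probability
#' `skeleton[j]^exp(beta)` given binary toxicity data, with
#' `beta ~ Normal(0, prior_sd^2)`, computed by one-dimensional numerical
#' integration. The power model preserves dose ordering for any data, so the
#' estimates are strictly increasing across doses.
#'
#' @param skeleton strictly increasing prior toxicity guesses in (0,1).
#' @param prior_sd prior standard deviation of the model parameter.
#' @param assignments integer dose index per treated patient (may be empty:
#'   the prior means are returned).
#' @param dlt 0/1 dose-limiting-toxicity outcome per patient, aligned with
#'   `assignments`.
#' @return Numeric vector of posterior toxicity probabilities, one per dose.
#' @examples
#' posterior_tox_estimates(c(0.05, 0.12, 0.25, 0.40, 0.55, 0.68), 1.34,
#'                         assignments = c(3, 3, 4), dlt = c(0, 0, 1))
#' @export
posterior_tox_estimates <- function(skeleton, prior_sd,
                                    assignments = integer(0),
                                    dlt = integer(0)) {
  check_skeleton(skeleton)
  if (length(assignments) != length(dlt)) {
    stop("'assignments' and 'dlt' must have equal length", call. = FALSE)
  }
  if (length(dlt) && !all(dlt %in% c(0, 1))) {
    stop("'dlt' must be binary", call. = FALSE)
  }
  if (length(assignments) &&
      (any(assignments < 1) || any(assignments > length(skeleton)))) {
    stop("'assignments' must be valid dose indices", call. = FALSE)
  }
  j <- length(skeleton)
  quad <- crm_quadrature(skeleton, prior_sd)
  n_dlt <- tabulate(assignments[dlt == 1], nbins = j)
  n_nodlt <- tabulate(assignments[dlt == 0], nbins = j)
  posterior_from_counts(quad, n_dlt, n_nodlt)
}

#' Next dose assignment
#'
#' The model-recommended dose minimizes the absolute distance between the
#' estimated toxicity and the target; ties (within numerical tolerance) break
#' toward the lower dose. With `no_skip`, the assignment is clamped to at
#' most one level above the highest dose tried so far.
#'
#' @param tox_estimates increasing per-dose toxicity estimates.
#' @param tox_target target toxicity probability.
#' @param current_dose index of the dose assigned to the previous patient.
#' @param max_tried highest dose index tried so far.
#' @param no_skip forbid skipping untried levels upward.
#' @return A dose index.
#' @export
next_dose <- function(tox_estimates, tox_target, current_dose, max_tried,
                      no_skip = TRUE) {
  d <- abs(tox_estimates - tox_target)
  best <- which(d <= min(d) + 1e-12)[1L]
  if (isTRUE(no_skip)) best <- min(best, max_tried + 1L, length(tox_estimates))
  as.integer(best)
}

#' Simulate one CRM trial
#'
#' Assigns patients one at a time starting at `start_dose`; each toxicity
#' outcome is Bernoulli with the scenario's true probability at the assigned
#' dose, the posterior is refit after every patient, and the next dose comes
#' from [next_dose()]. At the end, the MTD is the highest dose with posterior
#' toxicity estimate at or below `tox_target`; no dose is selected when the
#' lowest dose exceeds it (the safety gate that can discontinue the segment).
#'
#' @param design a [crm_design()].
#' @param scenario a [dose_scenario()] supplying true per-dose toxicity
#'   probabilities (response probabilities are not used by the phase I
#'   trial, whose decisions are toxicity-driven).
#' @return An object of class `crm_result`: list with `assignments`, `dlt`,
#'   `tox_estimates`, and `selected_dose` (`NA` for none).
#' @examples
#' set.seed(1)
#' run_crm_trial(crm_design(20), make_default_dose_scenario())
#' @export
run_crm_trial <- function(design, scenario) {
  stopifnot(inherits(design, "crm_design"), inherits(scenario, "dose_scenario"))
  if (length(scenario$tox) != design$n_doses) {
    stop("scenario must supply one toxicity probability per design dose",
         call. = FALSE)
  }
  quad <- crm_quadrature(design$skeleton, design$prior_sd)
  n1 <- design$n1
  assignments <- integer(n1)
  dlt <- integer(n1)
  n_dlt <- integer(design$n_doses)
  n_nodlt <- integer(design$n_doses)
  d <- design$start_dose
  est <- NULL
  for (i in seq_len(n1)) {
    assignments[i] <- d
    y <- rbinom(1L, 1L, scenario$tox[d])
    dlt[i] <- y
    if (y == 1L) n_dlt[d] <- n_dlt[d] + 1L else n_nodlt[d] <- n_nodlt[d] + 1L
    est <- posterior_from_counts(quad, n_dlt, n_nodlt)
    d <- next_dose(est, design$tox_target, d, max(assignments[seq_len(i)]),
                   design$no_skip)
  }
  acceptable <- which(est <= design$tox_target)
  selected <- if (length(acceptable) == 0L) NA_integer_ else max(acceptable)
  structure(
    list(assignments = assignments, dlt = dlt, tox_estimates = est,
         selected_dose = selected),
    class = "crm_result"
  )
}

#' Optimal dose (OD) selection rule
#'
#' Among doses with estimated toxicity at or below the target, returns the
#' dose with the highest estimated response rate (ties break toward the lower
#' dose); `NA` when no dose has acceptable toxicity. Unlike the MTD rule,
#' this can pick an interior dose when dose-response is non-monotone.
#'
#' @param tox_estimates per-dose toxicity estimates.
#' @param orr_estimates per-dose response-rate estimates.
#' @param tox_target maximum acceptable toxicity.
#' @return A dose index, or `NA_integer_`.
#' @examples
#' select_optimal_dose(c(0.1, 0.2, 0.3), c(0.2, 0.5, 0.9), 0.25) # dose 2
#' @export
select_optimal_dose <- function(tox_estimates, orr_estimates, tox_target) {
  if (length(tox_estimates) != length(orr_estimates)) {
    stop("estimate vectors must be aligned", call. = FALSE)
  }
  acceptable <- which(tox_estimates <= tox_target)
  if (length(acceptable) == 0L) return(NA_integer_)
  acceptable[which.max(orr_estimates[acceptable])]
}
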