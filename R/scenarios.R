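#' Dose-toxicity / dose-response truth scenario
#'
#' The ground-truth model for phase I/II simulations: one true
#' dose-limiting-toxicity (DLT) probability and one true objective response
#' rate (ORR) per dose level.
#'
#' @param tox per-dose true DLT probabilities, in `[0,1]`.
#' @param orr per-dose true ORRs, same length.
#' @return An object of class `dose_scenario` with fields `tox`, `orr`,
#'   `labels` (dose indices).
#' @export
dose_scenario <- function(tox, orr) {
  if (!is.numeric(tox) || !is.numeric(orr) || length(tox) != length(orr) ||
      length(tox) < 1L) {
    stop("'tox' and 'orr' must be numeric vectors of equal positive length",
         call. = FALSE)
  }
  if (any(tox < 0 | tox > 1) || any(orr < 0 | orr > 1)) {
    stop("scenario probabilities must lie in [0,1]", call. = FALSE)
  }
  structure(
    list(tox = as.numeric(tox), orr = as.numeric(orr),
         labels = seq_along(tox)),
    class = "dose_scenario"
  )
}

#' Biomarker-response truth scenario
#'
#' Truth model for enrichment simulations: the experimental response
#' probability is a function `orr1_fn(x)` of a biomarker `x` uniformly
#' distributed on `[biomarker_lower, 1)`, while the control (standard of
#' care) response probability `orr0` is constant in the biomarker.
#'
#' @param orr1_fn vectorized function mapping biomarker values in `[0,1]` to
#'   experimental response probabilities.
#' @param orr0 constant control response probability.
#' @param biomarker_lower lower bound of the uniform biomarker distribution
#'   (0 for an unselected phase II population; the selected cutoff for an
#'   enriched phase III population).
#' @param params optional named list recording the curve parameters, kept for
#'   lossless config serialization.
#' @return An object of class `biomarker_scenario`.
#' @export
biomarker_scenario <- function(orr1_fn, orr0 = 0.4, biomarker_lower = 0,
                               params = NULL) {
  stopifnot(is.function(orr1_fn))
  check_prob(orr0, "orr0")
  if (!is.numeric(biomarker_lower) || biomarker_lower < 0 ||
      biomarker_lower >= 1) {
    stop("'biomarker_lower' must lie in [0,1)", call. = FALSE)
  }
  probe <- orr1_fn(seq(0, 1, length.out = 11))
  if (any(!is.finite(probe)) || any(probe < 0 | probe > 1)) {
    stop("'orr1_fn' must return probabilities in [0,1] on [0,1]",
         call. = FALSE)
  }
  structure(
    list(orr1_fn = orr1_fn, orr0 = orr0, biomarker_lower = biomarker_lower,
         params = params),
    class = "biomarker_scenario"
  )
}

#' Enrollment and follow-up model for segment duration
#'
#' Linear-accrual timing model: each trial takes (patients / accrual rate)
#' months to enroll plus a fixed follow-up window, and consecutive trials are
#' separated by a planning gap. The default rates (4 patients/month in the
#' first trial, 10 in the second, 6-month gap and follow-ups) are package
#' defaults chosen as plausible oncology values and are fully
#' config-overridable.
#'
#' @param rate_a,rate_b accrual rates (patients/month) of the first and
#'   second trial; must be positive.
#' @param gap_months white space between a positive first trial and the
#'   start of the second.
#' @param followup_a,followup_b assessment windows (months) after the last
#'   patient of each trial.
#' @return An object of class `enrollment_model`.
#' @export
enrollment_model <- function(rate_a = 4, rate_b = 10, gap_months = 6,
                             followup_a = 6, followup_b = 6) {
  vals <- c(rate_a = rate_a, rate_b = rate_b, gap_months = gap_months,
            followup_a = followup_a, followup_b = followup_b)
  if (any(!is.finite(vals)) || any(vals < 0) || rate_a <= 0 || rate_b <= 0) {
    stop("enrollment parameters must be non-negative with positive rates",
         call. = FALSE)
  }
  structure(as.list(vals), class = "enrollment_model")
}

#' Response-rate truth for the phase II to phase III segment
#'
#' The standard scenario has an effective experimental treatment
#' (`ORR1 = 0.6`) against the historical standard of care (`ORR0 = 0.4`);
#' the null variant (`null = TRUE`) sets both to 0.4 for type-I-error
#' studies.
#'
#' @param null if `TRUE`, return the global-null variant.
#' @return A list with `orr1` and `orr0`.
#' @export
make_example1_scenario <- function(null = FALSE) {
  list(orr1 = if (isTRUE(null)) 0.4 else 0.6, orr0 = 0.4)
}

#' Default six-dose truth scenario
#'
#' Six dose levels with strictly increasing toxicity and non-decreasing
#' response, built so that exactly doses 3 and 4 are both safe (true DLT
#' probability at most 0.25) and effective (true ORR above 0.4): doses 1-2
#' are safe but ineffective, doses 5-6 effective but too toxic. The specific
#' probabilities are package fixture values satisfying those qualitative
#' constraints.
#'
#' @return A [dose_scenario()].
#' @export
make_default_dose_scenario <- function() {
  dose_scenario(
    tox = c(0.02, 0.06, 0.12, 0.20, 0.35, 0.50),
    orr = c(0.15, 0.30, 0.50, 0.60, 0.65, 0.67)
  )
}

#' Non-monotone dose-response truth scenario
#'
#' Toxicity increases with dose but response peaks at an interior dose, the
#' setting that motivates optimal-dose (OD) selection over MTD selection: on
#' the true values, [select_optimal_dose()] picks the response-maximizing
#' acceptable dose while the MTD rule picks a higher, less effective one.
#'
#' @return A [dose_scenario()].
#' @export
make_nonmonotone_dose_scenario <- function() {
  dose_scenario(
    tox = c(0.05, 0.10, 0.15, 0.22, 0.35, 0.50),
    orr = c(0.25, 0.45, 0.60, 0.50, 0.45, 0.40)
  )
}

#' Default biomarker-response truth scenario
#'
#' A logistic experimental response curve that crosses the constant
#' standard-of-care rate (0.4) exactly at biomarker value 0.6: patients with
#' biomarker at or above 0.6 benefit from the experimental treatment, those
#' below do better on the standard of care. The logistic slope (default 5 on
#' the logit scale) is a package fixture value; the crossing point and the
#' control rate define the scenario.
#'
#' @param crossing biomarker value where the curves cross.
#' @param slope logistic slope of the experimental curve on the logit scale.
#' @param orr0 constant control response probability.
#' @return A [biomarker_scenario()].
#' @export
make_default_biomarker_scenario <- function(crossing = 0.6, slope = 5,
                                            orr0 = 0.4) {
  check_prob(orr0, "orr0", lower_open = TRUE, upper_open = TRUE)
  a <- qlogis(orr0) - crossing * slope
  biomarker_scenario(
    orr1_fn = function(x) plogis(a + slope * x),
    orr0 = orr0,
    params = list(type = "logistic", crossing = crossing, slope = slope,
                  orr0 = orr0)
  )
}

#' Null biomarker scenario (no benefit anywhere)
#'
#' Experimental response equals the control rate at every biomarker value;
#' used to check segment-level false-positive rates.
#'
#' @param orr0 common response probability.
#' @return A [biomarker_scenario()].
#' @export
make_null_biomarker_scenario <- function(orr0 = 0.4) {
  force(orr0)
  biomarker_scenario(
    orr1_fn = function(x) rep(orr0, length(x)),
    orr0 = orr0,
    params = list(type = "flat", orr0 = orr0)
  )
}

#' Sample biomarker values
#'
#' Uniform draws on `[lower, 1)` using the current RNG state; `lower` is 0
#' for an unselected population and the selected cutoff for an enriched one.
#'
#' @param lower lower bound in `[0,1)`.
#' @param n number of draws.
#' @return Numeric vector of length `n`.
#' @export
sample_biomarker <- function(lower, n = 1L) {
  if (lower < 0 || lower >= 1) stop("'lower' must lie in [0,1)", call. = FALSE)
  lower + (1 - lower) * runif(n)
}

#' Duration of a DDP segment in months
#'
#' Accrual time plus follow-up of the first trial; when a second trial runs,
#' adds the between-trial gap and the second trial's accrual and follow-up.
#'
#' @param n_first patients in the first trial.
#' @param n_second patients in the second trial, or `NULL` when the segment
#'   stops after the first trial.
#' @param model an [enrollment_model()].
#' @return Duration in months.
#' @examples
#' segment_duration(60, 300, enrollment_model()) # 63 months
#' @export
segment_duration <- function(n_first, n_second = NULL, model = enrollment_model()) {
  stopifnot(inherits(model, "enrollment_model"))
  if (n_first < 0 || (!is.null(n_second) && n_second < 0)) {
    stop("patient counts must be non-negative", call. = FALSE)
  }
  dur <- n_first / model$rate_a + model$followup_a
  if (!is.null(n_second)) {
    dur <- dur + model$gap_months + n_second / model$rate_b + model$followup_b
  }
  dur
}
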