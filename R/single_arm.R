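#' Single-arm phase II trial design (one-sided exact binomial test)
#'
#' The trial enrolls `n2` patients, observes binary tumor responses, and
#' tests `H0: ORR <= orr0` against a one-sided alternative with an exact
#' binomial test at level `alpha`: the null is rejected when the observed
#' response count reaches [critical_value()].
#'
#' @param n2 number of patients (>= 1).
#' @param orr0 reference (standard-of-care) response probability under the
#'   null, in (0,1).
#' @param orr1_alt alternative response probability used for power and
#'   sample-size calculations; must exceed `orr0`.
#' @param alpha one-sided significance level in (0,1).
#' @return An object of class `single_arm_design`.
#' @examples
#' d <- single_arm_design(42)
#' exact_power(d$n2, d$orr0, d$orr1_alt, d$alpha)
#' @export
single_arm_design <- function(n2, orr0 = 0.4, orr1_alt = 0.6, alpha = 0.05) {
  n2 <- check_count(n2, "n2")
  check_prob(orr0, "orr0", lower_open = TRUE, upper_open = TRUE)
  check_prob(orr1_alt, "orr1_alt", lower_open = TRUE)
  check_prob(alpha, "alpha", lower_open = TRUE, upper_open = TRUE)
  if (orr1_alt <= orr0) {
    stop("'orr1_alt' must exceed 'orr0'", call. = FALSE)
  }
  structure(
    list(n2 = n2, orr0 = orr0, orr1_alt = orr1_alt, alpha = alpha),
    class = "single_arm_design"
  )
}

#' @export
print.single_arm_design <- function(x, ...) {
  r <- critical_value(x$n2, x$orr0, x$alpha)
  cat(sprintf(
    "Single-arm design: n2 = %d, H0: ORR <= %g, alternative ORR = %g, one-sided alpha = %g\n",
    x$n2, x$orr0, x$orr1_alt, x$alpha
  ))
  if (r <= x$n2) {
    cat(sprintf("Reject H0 when responses >= %d (power at alternative: %.3f)\n",
                r, exact_power(x$n2, x$orr0, x$orr1_alt, x$alpha)))
  } else {
    cat("No rejection region exists at this level.\n")
  }
  invisible(x)
}

#' Critical value of the one-sided exact binomial test
#'
#' Smallest integer `r` such that `P(X >= r) <= alpha` for
#' `X ~ Binomial(n, p0)`. Observing at least `r` responses rejects
#' `H0: p <= p0`; equivalently, the one-sided exact p-value is at most
#' `alpha`, with ties at exactly `alpha` rejecting.
#'
#' @param n number of patients.
#' @param p0 null response probability, in (0,1).
#' @param alpha one-sided level, in (0,1).
#' @return Integer in `0:(n+1)`; `n + 1` means no rejection region exists
#'   (even `n` responses out of `n` would not reject).
#' @examples
#' critical_value(42, 0.4, 0.05) # 23
#' critical_value(1, 0.4, 0.05)  # 2: rejection impossible
#' @export
critical_value <- function(n, p0, alpha) {
  n <- check_count(n, "n")
  check_prob(p0, "p0", lower_open = TRUE, upper_open = TRUE)
  check_prob(alpha, "alpha", lower_open = TRUE, upper_open = TRUE)
  r <- 0:n
  tail <- pbinom(r - 1, n, p0, lower.tail = FALSE) # P(X >= r), decreasing in r
  hit <- which(tail <= alpha)
  if (length(hit) == 0L) return(n + 1L)
  r[hit[1L]]
}

#' Exact power of the one-sided exact binomial test
#'
#' `P(X >= r | X ~ Binomial(n, p1))` where `r = critical_value(n, p0, alpha)`;
#' 0 when no rejection region exists. With `p1 = p0` this is the exact size of
#' the test, which is at most `alpha` (exact tests are conservative).
#'
#' @inheritParams critical_value
#' @param p1 true response probability at which power is evaluated, in (0,1].
#' @return Power in `[0, 1]`.
#' @examples
#' exact_power(42, 0.4, 0.6, 0.05) # about 0.803
#' @export
exact_power <- function(n, p0, p1, alpha) {
  check_prob(p1, "p1", lower_open = TRUE)
  r <- critical_value(n, p0, alpha)
  if (r > n) return(0)
  pbinom(r - 1, n, p1, lower.tail = FALSE)
}

#' Smallest sample size reaching a target exact binomial power
#'
#' Scans `n` linearly over `[n_min, n_max]` and returns the first `n` whose
#' exact power reaches `target_power`. The scan is linear because exact-test
#' power is a sawtooth in `n` (adding a patient can lower power when the
#' critical value jumps), so bisection is not valid.
#'
#' @inheritParams exact_power
#' @param target_power required power in (0,1).
#' @param n_min,n_max inclusive search range.
#' @return The smallest qualifying `n`; errors if no `n` in range qualifies.
#' @examples
#' minimum_sample_size(0.4, 0.6, 0.05, 0.8, 10, 200) # 42
#' @export
minimum_sample_size <- function(p0, p1, alpha, target_power, n_min, n_max) {
  check_prob(target_power, "target_power", lower_open = TRUE, upper_open = TRUE)
  n_min <- check_count(n_min, "n_min")
  n_max <- check_count(n_max, "n_max")
  if (n_min > n_max) stop("'n_min' must not exceed 'n_max'", call. = FALSE)
  for (n in n_min:n_max) {
    if (exact_power(n, p0, p1, alpha) >= target_power) return(n)
  }
  stop(sprintf(
    "target power %g unachievable for p0 = %g vs p1 = %g with n in [%d, %d]",
    target_power, p0, p1, n_min, n_max
  ), call. = FALSE)
}

#' Simulate one single-arm trial
#'
#' Draws the response count from `Binomial(n2, true_orr)` (and, optionally,
#' an independent toxicity count from `Binomial(n2, true_tox)`) using the
#' current RNG state, and applies the exact binomial rejection rule of the
#' design.
#'
#' @param design a [single_arm_design()].
#' @param true_orr true response probability generating the data.
#' @param true_tox optional true toxicity probability; when `NULL`,
#'   toxicities are not simulated and reported as 0.
#' @return An object of class `single_arm_result`: a list with `responses`,
#'   `orr_hat` (`responses / n2`), `reject`, and `toxicities`.
#' @examples
#' set.seed(1)
#' run_single_arm_trial(single_arm_design(42), true_orr = 0.6)
#' @export
run_single_arm_trial <- function(design, true_orr, true_tox = NULL) {
  stopifnot(inherits(design, "single_arm_design"))
  check_prob(true_orr, "true_orr")
  responses <- rbinom(1L, design$n2, true_orr)
  toxicities <- if (is.null(true_tox)) {
    0L
  } else {
    check_prob(true_tox, "true_tox")
    rbinom(1L, design$n2, true_tox)
  }
  r <- critical_value(design$n2, design$orr0, design$alpha)
  structure(
    list(
      responses = responses,
      orr_hat = responses / design$n2,
      reject = responses >= r,
      toxicities = toxicities
    ),
    class = "single_arm_result"
  )
}
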