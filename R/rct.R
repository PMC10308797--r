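#' Two-arm RCT design template (one-sided Fisher exact test)
#'
#' Describes a 1:1 randomized controlled trial analyzed by a one-sided Fisher
#' exact test. `n_per_arm` may be left `NULL` for a template whose size is
#' chosen at run time from earlier-trial estimates via [phase3_sample_size()],
#' subject to the `max_total` cap.
#'
#' @param n_per_arm patients per arm, or `NULL` for data-driven sizing.
#' @param alpha one-sided significance level.
#' @param target_power power targeted by the sample-size calculation.
#' @param max_total hard cap on total (both-arm) enrollment; totals are kept
#'   even, so the per-arm cap is `max_total %/% 2`.
#' @param sizing `"exact"` (default) sizes by exact unconditional Fisher
#'   power; `"normal"` by the two-proportion normal-approximation formula, a
#'   switch for sensitivity analyses of the sizing convention.
#' @return An object of class `rct_design`.
#' @export
rct_design <- function(n_per_arm = NULL, alpha = 0.05, target_power = 0.90,
                       max_total = 400, sizing = c("exact", "normal")) {
  sizing <- match.arg(sizing)
  check_prob(alpha, "alpha", lower_open = TRUE, upper_open = TRUE)
  check_prob(target_power, "target_power", lower_open = TRUE, upper_open = TRUE)
  max_total <- check_count(max_total, "max_total", min = 2L)
  if (!is.null(n_per_arm)) {
    n_per_arm <- check_count(n_per_arm, "n_per_arm")
    if (2L * n_per_arm > max_total) {
      stop("2 * n_per_arm must not exceed max_total", call. = FALSE)
    }
  }
  structure(
    list(n_per_arm = n_per_arm, alpha = alpha,
         target_power = target_power, max_total = max_total,
         sizing = sizing),
    class = "rct_design"
  )
}

#' One-sided Fisher exact p-value
#'
#' P-value of Fisher's exact test against the alternative that the
#' experimental arm has the higher response probability: the hypergeometric
#' upper-tail probability of observing at least `x1` experimental responders,
#' conditional on the table margins.
#'
#' @param x1,n1 responders and size of the experimental arm.
#' @param x0,n0 responders and size of the control arm.
#' @return p-value in (0, 1].
#' @examples
#' fisher_one_sided_pvalue(5, 5, 0, 5) # 1/252
#' @export
fisher_one_sided_pvalue <- function(x1, n1, x0, n0) {
  n1 <- check_count(n1, "n1")
  n0 <- check_count(n0, "n0")
  x1 <- check_count(x1, "x1", min = 0L)
  x0 <- check_count(x0, "x0", min = 0L)
  if (x1 > n1 || x0 > n0) stop("response counts exceed arm sizes", call. = FALSE)
  phyper(x1 - 1, n1, n0, x1 + x0, lower.tail = FALSE)
}

# Logical rejection region of the one-sided Fisher test over all outcome
# tables (x1, x0) in 0:n x 0:n, cached per (n, alpha): the region depends on
# the design only, not on the true response rates, so power evaluation at any
# (p1, p0) reduces to a bilinear form in two binomial pmf vectors.
fisher_rejection_region <- function(n_per_arm, alpha) {
  key <- sprintf("fisher_rej_%d_%.12g", n_per_arm, alpha)
  rej <- .ddpsim_cache[[key]]
  if (is.null(rej)) {
    x <- 0:n_per_arm
    pv <- outer(x, x, function(a, b) {
      phyper(a - 1, n_per_arm, n_per_arm, a + b, lower.tail = FALSE)
    })
    rej <- (pv <= alpha) * 1
    .ddpsim_cache[[key]] <- rej
  }
  rej
}

#' Exact unconditional power of the one-sided Fisher exact test
#'
#' Sums the joint probability `Binomial(n, p1) x Binomial(n, p0)` of all
#' outcome tables whose one-sided Fisher p-value is at most `alpha`. With
#' `p1 = p0` this is the exact size, which is at most `alpha`.
#'
#' @param n_per_arm patients per arm.
#' @param p1,p0 true response probabilities in the experimental and control
#'   arm.
#' @param alpha one-sided level.
#' @return Power in `[0, 1]`.
#' @examples
#' exact_unconditional_power(116, 0.6, 0.4, 0.05) # just above 0.90
#' @export
exact_unconditional_power <- function(n_per_arm, p1, p0, alpha) {
  n_per_arm <- check_count(n_per_arm, "n_per_arm")
  check_prob(p1, "p1")
  check_prob(p0, "p0")
  check_prob(alpha, "alpha", lower_open = TRUE, upper_open = TRUE)
  rej <- fisher_rejection_region(n_per_arm, alpha)
  d1 <- dbinom(0:n_per_arm, n_per_arm, p1)
  d0 <- dbinom(0:n_per_arm, n_per_arm, p0)
  as.numeric(d1 %*% rej %*% d0)
}

#' Data-driven phase III per-arm sample size under a cap
#'
#' Smallest per-arm size whose exact unconditional Fisher power at
#' `(p1_hat, p0_ref)` reaches `target_power`, subject to the total cap. The
#' scan over `n` is linear from 2 upward because exact power is a sawtooth in
#' `n`. When even the capped size misses the target, the trial still runs at
#' the cap (`max_total %/% 2` per arm) with `capped = TRUE`: the cap limits
#' the trial size, not the decision to run it.
#'
#' Results are memoized (optionally in a caller-supplied environment) since
#' `p1_hat`, being an observed response fraction, takes few distinct values
#' across the replicates of a simulation run.
#'
#' @param p1_hat estimated experimental response probability (must exceed
#'   `p0_ref`; upstream gating guarantees this for rejecting phase II trials).
#' @param p0_ref reference control response probability.
#' @param alpha one-sided level of the phase III test.
#' @param target_power targeted power.
#' @param max_total total-enrollment cap.
#' @param method `"exact"` for exact unconditional Fisher power (default) or
#'   `"normal"` for the two-proportion normal-approximation sample-size
#'   formula (sensitivity switch; the cap still applies).
#' @param cache optional environment used to memoize results.
#' @return A list with `n_per_arm`, `capped`, and `power` (exact power at the
#'   returned size).
#' @examples
#' phase3_sample_size(0.6, 0.4)$n_per_arm # 116
#' phase3_sample_size(0.45, 0.4)$capped   # TRUE: 400-patient cap binds
#' @export
phase3_sample_size <- function(p1_hat, p0_ref, alpha = 0.05,
                               target_power = 0.90, max_total = 400,
                               method = c("exact", "normal"),
                               cache = NULL) {
  method <- match.arg(method)
  check_prob(p1_hat, "p1_hat")
  check_prob(p0_ref, "p0_ref")
  if (p1_hat <= p0_ref) {
    stop("'p1_hat' must exceed 'p0_ref' for a superiority sample size",
         call. = FALSE)
  }
  key <- sprintf("p3n_%.12g_%.12g_%.12g_%.12g_%d_%s",
                 p1_hat, p0_ref, alpha, target_power, max_total, method)
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  n_cap <- as.integer(max_total %/% 2)
  if (method == "normal") {
    n_norm <- ceiling(
      (qnorm(1 - alpha) + qnorm(target_power))^2 *
        (p1_hat * (1 - p1_hat) + p0_ref * (1 - p0_ref)) /
        (p1_hat - p0_ref)^2
    )
    n <- min(max(2L, as.integer(n_norm)), n_cap)
    out <- list(n_per_arm = n, capped = n_norm > n_cap,
                power = exact_unconditional_power(n, p1_hat, p0_ref, alpha))
    if (!is.null(cache)) cache[[key]] <- out
    return(out)
  }
  out <- if (exact_unconditional_power(n_cap, p1_hat, p0_ref, alpha) <
             target_power) {
    list(n_per_arm = n_cap, capped = TRUE,
         power = exact_unconditional_power(n_cap, p1_hat, p0_ref, alpha))
  } else {
    n <- 2L
    repeat {
      pw <- exact_unconditional_power(n, p1_hat, p0_ref, alpha)
      if (pw >= target_power || n >= n_cap) break
      n <- n + 1L
    }
    list(n_per_arm = n, capped = FALSE, power = pw)
  }
  if (!is.null(cache)) cache[[key]] <- out
  out
}

#' Simulate one two-arm RCT
#'
#' Draws the two arms independently from `Binomial(n_per_arm, .)` using the
#' current RNG state and applies the one-sided Fisher exact test.
#'
#' @param n_per_arm patients per arm.
#' @param true_p1,true_p0 true response probabilities.
#' @param alpha one-sided level.
#' @return An object of class `rct_result`: list with `x_exp`, `x_ctl`,
#'   `p_value`, `reject`.
#' @examples
#' set.seed(1)
#' run_rct(116, 0.6, 0.4)
#' @export
run_rct <- function(n_per_arm, true_p1, true_p0, alpha = 0.05) {
  n_per_arm <- check_count(n_per_arm, "n_per_arm")
  check_prob(true_p1, "true_p1")
  check_prob(true_p0, "true_p0")
  x1 <- rbinom(1L, n_per_arm, true_p1)
  x0 <- rbinom(1L, n_per_arm, true_p0)
  p <- fisher_one_sided_pvalue(x1, n_per_arm, x0, n_per_arm)
  structure(
    list(x_exp = x1, x_ctl = x0, p_value = p, reject = p <= alpha),
    class = "rct_result"
  )
}
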