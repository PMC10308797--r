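`%||%` <- function(a, b) if (is.null(a)) b else a

check_prob <- function(x, name, lower_open = FALSE, upper_open = FALSE) {
  lo_ok <- if (lower_open) x > 0 else x >= 0
  hi_ok <- if (upper_open) x < 1 else x <= 1
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || !lo_ok || !hi_ok) {
    stop(sprintf(
      "'%s' must be a single probability in %s0,1%s (got %s)",
      name, if (lower_open) "(" else "[", if (upper_open) ")" else "]",
      paste(format(x), collapse = ",")
    ), call. = FALSE)
  }
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x < min || x != round(x)) {
    stop(sprintf("'%s' must be an integer >= %d (got %s)",
                 name, min, paste(format(x), collapse = ",")), call. = FALSE)
  }
  invisible(as.integer(x))
}

#' Derive a reproducible per-replicate seed
#'
#' Maps a base seed and a replicate index to an integer seed below 2^31 via a
#' Lehmer-style multiplicative step, so that replicate `i` of a run is
#' reproducible in isolation and independent of execution order. Splitting a
#' run into consecutive blocks of replicate indices and pooling the results
#' reproduces the full run exactly.
#'
#' @param seed integer base seed of the run.
#' @param i replicate index (1-based).
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
rep_seed <- function(seed, i) {
  m <- 2147483647 # 2^31 - 1 (prime)
  s <- (48271 * ((as.double(seed) %% m) + as.double(i))) %% m
  as.integer(if (s == 0) 1 else s)
}

# standard error of a proportion estimated from n Monte-Carlo replicates
prop_se <- function(p, n) if (n > 1) sqrt(p * (1 - p) / n) else NA_real_

mean_se <- function(x) {
  if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else NA_real_
}
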