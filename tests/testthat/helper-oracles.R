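# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: tails are accumulated by explicit summation of
# pmf terms, Fisher p-values by conditional enumeration of tables, and the
# CRM posterior by brute-force trapezoid integration on a dense grid.

enum_critical_value <- function(n, p0, alpha) {
  for (r in 0:n) {
    if (sum(dbinom(r:n, n, p0)) <= alpha) return(r)
  }
  n + 1L
}

enum_binom_power <- function(n, p0, p1, alpha) {
  r <- enum_critical_value(n, p0, alpha)
  if (r > n) 0 else sum(dbinom(r:n, n, p1))
}

# one-sided Fisher p-value by enumerating the conditional distribution of
# the experimental-arm count given the response margin
enum_fisher_p <- function(x1, n1, x0, n0) {
  m <- x1 + x0
  ks <- max(0, m - n0):min(n1, m)
  probs <- choose(n1, ks) * choose(n0, m - ks) / choose(n1 + n0, m)
  sum(probs[ks >= x1])
}

enum_fisher_power <- function(n, p1, p0, alpha) {
  total <- 0
  for (x1 in 0:n) {
    for (x0 in 0:n) {
      if (enum_fisher_p(x1, n, x0, n) <= alpha) {
        total <- total + dbinom(x1, n, p1) * dbinom(x0, n, p0)
      }
    }
  }
  total
}

# brute-force CRM posterior means: trapezoid rule on a dense grid
crm_posterior_oracle <- function(skeleton, prior_sd, assignments, dlt,
                                 n_grid = 1e5, lim = 10) {
  b <- seq(-lim, lim, length.out = n_grid)
  h <- b[2] - b[1]
  trap <- rep(1, n_grid); trap[1] <- trap[n_grid] <- 0.5
  lik <- vapply(b, function(bb) {
    if (!length(assignments)) return(1)
    p <- skeleton[assignments]^exp(bb)
    prod(ifelse(dlt == 1, p, 1 - p))
  }, 0)
  w <- lik * dnorm(b, 0, prior_sd) * trap * h
  vapply(skeleton, function(s) sum(s^exp(b) * w) / sum(w), 0)
}
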