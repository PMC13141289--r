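# Independent oracles used across tests: literal, unoptimized evaluations
# against which the package's vectorized / compiled paths are checked.

# brute-force CPM negative log-likelihood: product of per-observation cell
# probabilities evaluated with the plain link CDF and explicit sentinels
oracle_neg_loglik <- function(alpha, beta, tau, y, x, a, link) {
  link <- mwcpm::make_link(link)
  vals <- sort(unique(y))
  aext <- c(-Inf, alpha, Inf)
  ll <- 0
  for (i in seq_along(y)) {
    r <- match(y[i], vals)
    eta <- sum(beta * x[i, ]) + tau * a[i]
    up <- aext[r + 1] - eta
    lo <- aext[r] - eta
    p <- (if (is.finite(up)) link$cdf(up) else 1) -
         (if (is.finite(lo)) link$cdf(lo) else 0)
    ll <- ll + log(p)
  }
  -ll
}

# literal double-sum Mann-Whitney functional over two mass vectors
oracle_theta_double_sum <- function(support, p1, p0) {
  th <- 0
  for (k in seq_along(support)) {
    for (l in seq_along(support)) {
      h <- (support[k] > support[l]) + 0.5 * (support[k] == support[l])
      th <- th + h * p1[k] * p0[l]
    }
  }
  th
}

# literal pair enumeration of the empirical Mann-Whitney probability
oracle_theta_pairs <- function(y1, y0) {
  tot <- 0
  for (i in seq_along(y1)) {
    for (j in seq_along(y0)) {
      tot <- tot + (y1[i] > y0[j]) + 0.5 * (y1[i] == y0[j])
    }
  }
  tot / (length(y1) * length(y0))
}

# random small dataset with optional ties, for fuzzing
random_tiny_data <- function(n, seed, ties = FALSE) {
  set.seed(seed)
  y <- if (ties) sample(1:3, n, replace = TRUE) else rnorm(n)
  while (length(unique(y)) < 2) y <- sample(1:3, n, replace = TRUE)
  x <- matrix(rnorm(n), ncol = 1)
  a <- rep_len(c(0L, 1L), n)
  list(y = y, x = x, a = a,
       df = tibble::tibble(y = y, x = x[, 1], a = a))
}

# admissible random parameters for a dataset with K distinct values
random_params <- function(K, p, seed) {
  set.seed(seed)
  list(alpha = sort(rnorm(K - 1)), beta = rnorm(p) * 0.5,
       tau = rnorm(1) * 0.5)
}
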