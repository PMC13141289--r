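#' Step CDF objects
#'
#' A discrete cumulative distribution supported on the distinct observed
#' outcome values; the container for conditional and marginal
#' potential-outcome CDFs.
#'
#' @param support Strictly increasing numeric support.
#' @param cumprob Nondecreasing cumulative probabilities ending at 1.
#' @return A tibble of class `step_cdf` with columns `y` and `cumprob`.
#' @export
new_step_cdf <- function(support, cumprob) {
  stopifnot(length(support) == length(cumprob))
  out <- tibble::tibble(y = as.numeric(support), cumprob = as.numeric(cumprob))
  class(out) <- c("step_cdf", class(out))
  out
}

#' Marginal potential-outcome CDF by g-computation
#'
#' Standardizes the fitted conditional CDF over the empirical covariate
#' distribution of the *full* sample (both arms), with the treatment set to
#' `a` for everyone:
#' \eqn{\hat F_a(y_{(k)}) = n^{-1} \sum_{i=1}^n
#' F_\epsilon(\hat\alpha_k - \hat\beta' x_i - \hat\tau a)},
#' and \eqn{\hat F_a(y_{(K)}) = 1}. Under ignorability, consistency and
#' positivity this estimates the marginal CDF of the potential outcome
#' \eqn{Y(a)}.
#'
#' @param fit A `cpm_fit` carrying its model frame.
#' @param a Counterfactual treatment value, 0 or 1.
#' @return A `step_cdf` tibble.
#' @export
marginal_cdf <- function(fit, a) {
  stopifnot(inherits(fit, "cpm_fit"))
  if (!a %in% c(0, 1)) {
    rlang::abort("a must be 0 or 1", class = "mwcpm_config_error")
  }
  if (!isTRUE(fit$converged)) {
    rlang::warn("fit did not converge; marginal CDF may be unreliable",
                class = "mwcpm_nonconvergence")
  }
  md <- fit$model_data
  cp <- marginal_cdf_core(fit$alpha, fit$beta, fit$tau, md$x,
                          a, make_link(fit$link))
  new_step_cdf(fit$encoded$distinct_values, cp)
}

marginal_cdf_core <- function(alpha, beta, tau, x, a, link) {
  eta <- if (ncol(x) > 0) as.numeric(x %*% beta) else numeric(nrow(x))
  eta <- eta + tau * a
  # (K-1) x n matrix of alpha_k - eta_i, averaged over subjects
  m <- outer(alpha, eta, "-")
  cp <- c(rowMeans(link$cdf(m)), 1)
  cummax(pmin(pmax(cp, 0), 1))
}

#' Mann-Whitney-type effect from two marginal CDFs
#'
#' Computes \eqn{\theta = \sum_k \sum_l h(y_{(k)}, y_{(l)}) p_{1k} p_{0l}}
#' with kernel \eqn{h(y_1, y_0) = I(y_1 > y_0) + 0.5 I(y_1 = y_0)} and
#' \eqn{p_{ak}} the probability masses of the two step CDFs (the diagonal
#' \eqn{k = l} tie term is included). Evaluated in O(K) as
#' \eqn{\sum_l p_{0l} [(1 - F_1(y_{(l)})) + p_{1l}/2]}.
#'
#' @param f1,f0 `step_cdf` objects on the same support (treated and control
#'   marginal CDFs).
#' @return The effect estimate, a probability.
#' @examples
#' f1 <- new_step_cdf(1:3, cumsum(c(0.2, 0.3, 0.5)))
#' f0 <- new_step_cdf(1:3, cumsum(c(0.5, 0.3, 0.2)))
#' mw_theta_from_cdfs(f1, f0)  # 0.695
#' @export
mw_theta_from_cdfs <- function(f1, f0) {
  if (!isTRUE(all.equal(f1$y, f0$y, tolerance = 0))) {
    rlang::abort("the two step CDFs must share the same support grid",
                 class = "mwcpm_grid_mismatch")
  }
  p1 <- diff(c(0, f1$cumprob))
  p0 <- diff(c(0, f0$cumprob))
  sum(p0 * ((1 - f1$cumprob) + 0.5 * p1))
}

#' Unadjusted empirical Mann-Whitney probability
#'
#' The tie-corrected Mann-Whitney U statistic divided by `n1 * n0`: the
#' fraction of treated-control pairs with the treated outcome larger, plus
#' half the tied fraction. This is the estimate obtained by plugging the raw
#' group-specific empirical CDFs into the effect functional, with no
#' confounding adjustment.
#'
#' @param y_treated,y_control Nonempty numeric outcome vectors.
#' @return A probability.
#' @examples
#' mw_theta_empirical(c(3, 5), c(1, 3))  # 0.875
#' @export
mw_theta_empirical <- function(y_treated, y_control) {
  n1 <- length(y_treated); n0 <- length(y_control)
  if (n1 == 0 || n0 == 0) {
    rlang::abort("both groups must be nonempty", class = "mwcpm_data_error")
  }
  r <- rank(c(y_treated, y_control), ties.method = "average")
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  u / (n1 * n0)
}

#' Covariate-adjusted Mann-Whitney-type effect estimate
#'
#' The full plug-in pipeline: fit the CPM, form both counterfactual marginal
#' CDFs by g-computation, and evaluate the Mann-Whitney functional.
#' Deterministic given the data.
#'
#' @inheritParams fit_cpm
#' @param ... Passed to [fit_cpm()].
#' @return The point estimate (a probability in `[0, 1]`) with attributes
#'   `converged` and `loglik`.
#' @export
estimate_theta <- function(data, outcome = "y", treatment = "a",
                           covariates = NULL, link = "probit", ...) {
  md <- model_data(data, outcome, treatment, covariates)
  link <- as_mw_link(link)
  core <- estimate_theta_core(md$encoded, md$x, md$a, link, ...)
  structure(core$theta, converged = core$converged, loglik = core$loglik)
}

estimate_theta_core <- function(encoded, x, a, link, ...) {
  fit <- fit_cpm_core(encoded, x, a, link, ...)
  f1 <- marginal_cdf_core(fit$alpha, fit$beta, fit$tau, x, 1, link)
  f0 <- marginal_cdf_core(fit$alpha, fit$beta, fit$tau, x, 0, link)
  p1 <- diff(c(0, f1))
  p0 <- diff(c(0, f0))
  list(theta = sum(p0 * ((1 - f1) + 0.5 * p1)),
       converged = fit$converged, loglik = fit$loglik)
}

#' Bootstrap inference for the Mann-Whitney-type effect
#'
#' Nonparametric bootstrap: rows are resampled with replacement (optionally
#' within treatment arms), the whole estimation pipeline is re-run on each
#' resample, and the standard error is the standard deviation of the
#' replicate estimates. The default confidence interval is the
#' normal-approximation interval `theta +/- 1.96 * se`; a percentile
#' interval is available via `ci_type = "percentile"`. Replicates whose CPM
#' fails to converge, or that lose an arm or outcome variation entirely, are
#' dropped with a count kept in `n_boot_used`.
#'
#' @inheritParams estimate_theta
#' @param B Number of bootstrap replicates (at least 2).
#' @param seed Integer seed; the result is fully reproducible from it.
#' @param stratified Resample within treatment arms? Default `FALSE` (plain
#'   row resampling).
#' @param ci_type `"normal"` or `"percentile"`.
#' @param conf_level Confidence level (default 0.95; the normal interval uses
#'   the matching z quantile, 1.96 at 0.95).
#' @param ... Passed to the internal fitter.
#' @return An object of class `theta_estimate`: `theta`, `se`, `ci_low`,
#'   `ci_high`, `n_boot_requested`, `n_boot_used`, `seed`, the replicate
#'   estimates, and fit diagnostics.
#' @export
bootstrap_theta <- function(data, outcome = "y", treatment = "a",
                            covariates = NULL, link = "probit",
                            B = 200L, seed = 1L, stratified = FALSE,
                            ci_type = c("normal", "percentile"),
                            conf_level = 0.95, ...) {
  ci_type <- match.arg(ci_type)
  if (B < 2) rlang::abort("B must be at least 2", class = "mwcpm_config_error")
  md <- model_data(data, outcome, treatment, covariates)
  link <- as_mw_link(link)
  point <- estimate_theta_core(md$encoded, md$x, md$a, link, ...)

  y <- md$y; x <- md$x; a <- md$a
  n <- length(a)
  idx1 <- which(a == 1); idx0 <- which(a == 0)
  boot <- rep(NA_real_, B)
  set.seed(seed)
  for (b in seq_len(B)) {
    idx <- if (stratified) {
      c(sample(idx1, length(idx1), replace = TRUE),
        sample(idx0, length(idx0), replace = TRUE))
    } else {
      sample.int(n, n, replace = TRUE)
    }
    ab <- a[idx]
    yb <- y[idx]
    if (sum(ab) == 0 || sum(ab) == n || length(unique(yb)) < 2) next
    encb <- encode_outcome(yb)
    res <- tryCatch(
      estimate_theta_core(encb, x[idx, , drop = FALSE], ab, link, ...),
      error = function(e) NULL)
    if (!is.null(res) && isTRUE(res$converged)) boot[b] <- res$theta
  }
  ok <- boot[!is.na(boot)]
  if (length(ok) < 2) {
    rlang::abort("bootstrap inference failed: fewer than 2 usable replicates",
                 class = "mwcpm_inference_failure", theta = point$theta)
  }
  se <- stats::sd(ok)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  if (ci_type == "normal") {
    ci <- point$theta + c(-1, 1) * z * se
  } else {
    ci <- unname(stats::quantile(ok, c((1 - conf_level) / 2,
                                       1 - (1 - conf_level) / 2)))
  }
  structure(list(
    theta = point$theta, se = se,
    ci_low = ci[1], ci_high = ci[2],
    n_boot_requested = as.integer(B), n_boot_used = length(ok),
    seed = as.integer(seed), ci_type = ci_type, conf_level = conf_level,
    boot_estimates = ok,
    link = link$name, converged = point$converged, loglik = point$loglik,
    n = n, K = length(md$encoded$distinct_values)
  ), class = "theta_estimate")
}

#' @export
print.theta_estimate <- function(x, ...) {
  cat("Mann-Whitney-type causal effect (CPM,", x$link, "link)\n")
  cat(sprintf("  theta = %.4f  se = %.4f  %d%% CI (%s) = [%.4f, %.4f]\n",
              x$theta, x$se, round(100 * x$conf_level), x$ci_type,
              x$ci_low, x$ci_high))
  cat(sprintf("  bootstrap: %d of %d replicates used; seed %d\n",
              x$n_boot_used, x$n_boot_requested, x$seed))
  if (!isTRUE(x$converged)) cat("  warning: point-estimate fit did not converge\n")
  invisible(x)
}

#' @describeIn bootstrap_theta Tidy the estimate into a one-row tibble.
#' @param x A `theta_estimate` object.
#' @export
tidy.theta_estimate <- function(x, ...) {
  tibble::tibble(
    estimate = x$theta, std.error = x$se,
    conf.low = x$ci_low, conf.high = x$ci_high
  )
}

#' @describeIn bootstrap_theta One-row diagnostics summary.
#' @export
glance.theta_estimate <- function(x, ...) {
  tibble::tibble(
    estimate = x$theta, std.error = x$se, link = x$link,
    logLik = x$loglik, converged = x$converged, n = x$n, K = x$K,
    n_boot_requested = x$n_boot_requested, n_boot_used = x$n_boot_used,
    ci_type = x$ci_type, seed = x$seed
  )
}

#' @describeIn bootstrap_theta Histogram of bootstrap replicate estimates
#'   with the point estimate and interval marked.
#' @param object A `theta_estimate` object.
#' @export
autoplot.theta_estimate <- function(object, ...) {
  df <- tibble::tibble(theta = object$boot_estimates)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$theta)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = object$theta, colour = "firebrick") +
    ggplot2::geom_vline(xintercept = c(object$ci_low, object$ci_high),
                        linetype = "dashed") +
    ggplot2::labs(
      x = expression(hat(theta)),
      y = "bootstrap replicates",
      title = "Bootstrap distribution of the Mann-Whitney-type effect")
}

#' @describeIn new_step_cdf Step plot of a discrete CDF.
#' @param object A `step_cdf` object.
#' @param ... Unused.
#' @export
autoplot.step_cdf <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$y, y = .data$cumprob)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "outcome value", y = "cumulative probability")
}
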