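#' Transformed normal-linear-model comparator fit
#'
#' The parametric outcome-regression comparator: ordinary least squares of a
#' transformed outcome on covariates and treatment, assuming homoscedastic
#' normal errors on the transformed scale. With the log transform this is
#' exactly correct for a log-normal outcome model; the square-root transform
#' is the deliberately misspecified variant.
#'
#' @inheritParams fit_cpm
#' @param transform One of `"identity"`, `"log"`, `"sqrt"`.
#' @return An object of class `nlm_fit`: `transform`, `intercept`, `beta`,
#'   `tau`, `sigma` (residual SD with denominator `n - p - 2`), and the model
#'   frame pieces.
#' @export
fit_transformed_nlm <- function(data, outcome = "y", treatment = "a",
                                covariates = NULL,
                                transform = c("identity", "log", "sqrt")) {
  transform <- match.arg(transform)
  md <- model_data(data, outcome, treatment, covariates)
  ty <- apply_transform(md$y, transform)
  fit <- nlm_fit_core(ty, md$x, md$a, transform)
  fit$model_data <- md
  fit
}

apply_transform <- function(y, transform) {
  switch(transform,
    identity = as.numeric(y),
    log = {
      bad <- which(y <= 0)
      if (length(bad)) {
        rlang::abort(paste0(
          "log transform needs strictly positive outcomes; offending rows: ",
          paste(utils::head(bad, 10), collapse = ", "),
          if (length(bad) > 10) ", ..." else ""),
          class = "mwcpm_domain_error")
      }
      log(y)
    },
    sqrt = {
      bad <- which(y < 0)
      if (length(bad)) {
        rlang::abort(paste0(
          "sqrt transform needs nonnegative outcomes; offending rows: ",
          paste(utils::head(bad, 10), collapse = ", "),
          if (length(bad) > 10) ", ..." else ""),
          class = "mwcpm_domain_error")
      }
      sqrt(y)
    })
}

nlm_fit_core <- function(ty, x, a, transform) {
  df <- as.data.frame(x)
  p <- ncol(x)
  names(df) <- if (p > 0) paste0("x", seq_len(p)) else character(0)
  df$.a <- a
  df$.ty <- ty
  fml <- stats::as.formula(paste(".ty ~", paste(c(names(df)[seq_len(p)], ".a"),
                                                collapse = " + ")))
  lmfit <- stats::lm(fml, data = df)
  cf <- stats::coef(lmfit)
  s <- stats::sigma(lmfit)  # residual SD, denominator n - p - 2
  if (!is.finite(s)) s <- sqrt(mean(stats::residuals(lmfit)^2))  # saturated fit
  structure(list(
    transform = transform,
    intercept = unname(cf[1]),
    beta = unname(cf[seq_len(p) + 1]),
    tau = unname(cf[p + 2]),
    sigma = s,
    n = length(a), p = p
  ), class = "nlm_fit")
}

#' @export
print.nlm_fit <- function(x, ...) {
  cat("Transformed normal linear model (", x$transform, " scale )\n", sep = "")
  cat("  intercept:", signif(x$intercept, 4),
      " beta:", paste(signif(x$beta, 4), collapse = " "),
      " tau:", signif(x$tau, 4), " sigma:", signif(x$sigma, 4), "\n")
  invisible(x)
}

#' @describeIn fit_transformed_nlm Tidy the coefficients.
#' @param x An `nlm_fit` object.
#' @export
tidy.nlm_fit <- function(x, ...) {
  terms <- c("(Intercept)",
             if (x$p > 0) paste0("x", seq_len(x$p)) else character(0),
             "treatment")
  tibble::tibble(term = terms, estimate = c(x$intercept, x$beta, x$tau))
}

#' @describeIn fit_transformed_nlm One-row summary.
#' @export
glance.nlm_fit <- function(x, ...) {
  tibble::tibble(transform = x$transform, sigma = x$sigma, n = x$n, p = x$p)
}

#' Mann-Whitney-type effect from a transformed normal linear model
#'
#' Plug-in pairwise-normal estimator: under the fitted homoscedastic normal
#' model on the transformed scale, for subjects `i`, `j` drawn from the
#' empirical covariate distribution,
#' \deqn{\hat\theta = n^{-2} \sum_i \sum_j
#'   \Phi\{(\hat\tau + \hat\beta'(x_i - x_j)) / (\hat\sigma\sqrt 2)\}.}
#' A monotone transform of the outcome leaves the exceedance probability
#' unchanged, so no back-transformation is needed.
#'
#' @param fit An `nlm_fit` (carrying its model frame), from
#'   [fit_transformed_nlm()].
#' @param data Optional replacement data (data frame or `mw_model_data`)
#'   over whose covariates to standardize; defaults to the fit's own.
#' @param ... Passed to [model_data()] when `data` is a data frame.
#' @return The effect estimate, a probability. When the residual SD is zero
#'   the degenerate limit (indicator average) is returned with a warning.
#' @export
theta_from_nlm <- function(fit, data = NULL, ...) {
  stopifnot(inherits(fit, "nlm_fit"))
  md <- if (is.null(data)) fit$model_data else
    if (inherits(data, "mw_model_data")) data else model_data(data, ...)
  theta_from_nlm_core(fit$beta, fit$tau, fit$sigma, md$x)
}

theta_from_nlm_core <- function(beta, tau, sigma, x) {
  eta <- if (ncol(x) > 0) as.numeric(x %*% beta) else numeric(nrow(x))
  d <- tau + outer(eta, eta, "-")
  if (sigma <= 0) {
    rlang::warn("residual SD is zero; returning the degenerate limit",
                class = "mwcpm_degenerate_sigma")
    return(mean((d > 0) + 0.5 * (d == 0)))
  }
  mean(stats::pnorm(d / (sigma * sqrt(2))))
}
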