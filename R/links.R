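#' Link functions for cumulative probability models
#'
#' A link `G` in a cumulative probability model is the inverse of the CDF of
#' the latent error term: `G[P(Y <= y | X, A)] = alpha(y) - beta'X - tau*A`,
#' so `cdf` here is \eqn{G^{-1} = F_\epsilon} and `quantile` is \eqn{G}.
#' Supported links:
#' \describe{
#'   \item{`probit`}{standard normal errors.}
#'   \item{`logit`}{standard logistic errors (proportional odds).}
#'   \item{`loglog`}{Gumbel maximum-value errors, \eqn{F(x) = \exp(-e^{-x})},
#'     i.e. \eqn{G(p) = -\log(-\log p)}. This is the orientation used
#'     throughout the package wherever "loglog" appears.}
#'   \item{`cloglog`}{the mirrored (complementary log-log) convention,
#'     \eqn{F(x) = 1 - \exp(-e^{x})}, provided because ordinal-regression
#'     software is split between the two conventions.}
#' }
#'
#' @param name Link name, one of `"probit"`, `"logit"`, `"loglog"`,
#'   `"cloglog"`.
#' @return An object of class `mw_link`: a list with elements `name`,
#'   `cdf` (\eqn{F_\epsilon}), `quantile` (\eqn{G}), `density`
#'   (\eqn{f_\epsilon}) and an internal integer `code`.
#' @examples
#' lk <- make_link("probit")
#' lk$cdf(0)            # 0.5
#' lk$quantile(0.975)   # 1.959964
#' @export
make_link <- function(name) {
  name <- as.character(name)[1]
  switch(name,
    probit = structure(list(
      name = "probit", cdf = stats::pnorm, quantile = stats::qnorm,
      density = stats::dnorm, code = 0L), class = "mw_link"),
    logit = structure(list(
      name = "logit", cdf = stats::plogis, quantile = stats::qlogis,
      density = stats::dlogis, code = 1L), class = "mw_link"),
    loglog = structure(list(
      name = "loglog",
      cdf = function(q) exp(-exp(-q)),
      quantile = function(p) -log(-log(p)),
      density = function(x) exp(-x - exp(-x)),
      code = 2L), class = "mw_link"),
    cloglog = structure(list(
      name = "cloglog",
      cdf = function(q) -expm1(-exp(q)),
      quantile = function(p) log(-log1p(-p)),
      density = function(x) exp(x - exp(x)),
      code = 3L), class = "mw_link"),
    rlang::abort(
      paste0("Unsupported link '", name,
             "'. Available links: probit, logit, loglog, cloglog."),
      class = "mwcpm_unsupported_link")
  )
}

as_mw_link <- function(link) {
  if (inherits(link, "mw_link")) link else make_link(link)
}

#' @export
print.mw_link <- function(x, ...) {
  cat("<mw_link>", x$name, "\n")
  invisible(x)
}

#' Numerically stable cell probability under a link
#'
#' Computes `cdf(upper) - cdf(lower)` for a link's error distribution without
#' catastrophic cancellation when both bounds sit in the same far tail (the
#' difference is then taken between complementary CDF values). The bounds
#' `-Inf` and `+Inf` are the sentinels for the outermost cells of the
#' cumulative-link likelihood, for which the result is exactly `cdf(upper)`
#' and `1 - cdf(lower)` respectively. Finite bounds are clipped to
#' \eqn{[-38, 38]} before evaluation, and a positive floor prevents an exact
#' zero whenever `upper > lower`.
#'
#' @param link An `mw_link` object or link name.
#' @param upper,lower Extended-real cell bounds (vectors are recycled);
#'   each `upper` must strictly exceed its `lower`.
#' @return A numeric vector of probabilities in `(0, 1]`.
#' @examples
#' cell_probability(make_link("probit"), 1, -1)   # 0.682689
#' cell_probability(make_link("probit"), Inf, -Inf)  # 1
#' @export
cell_probability <- function(link, upper, lower) {
  link <- as_mw_link(link)
  n <- max(length(upper), length(lower))
  upper <- rep_len(as.numeric(upper), n)
  lower <- rep_len(as.numeric(lower), n)
  if (any(is.na(upper)) || any(is.na(lower))) {
    rlang::abort("cell bounds must not be NA", class = "mwcpm_bounds_error")
  }
  if (any(upper <= lower)) {
    rlang::abort("each `upper` bound must strictly exceed its `lower` bound",
                 class = "mwcpm_ordering_error")
  }
  .cell_prob_cpp(lower, upper, link$code)
}
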