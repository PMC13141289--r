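test_that("link CDFs, quantiles and densities are mutually consistent", {
  # Test ranges are capped where IEEE doubles can still represent the CDF
  # away from exactly 0 or 1: the loglog CDF underflows to 0 below about
  # -6.6, the cloglog CDF rounds to 1 above about 3.9, and the probit CDF
  # loses enough upper-tail resolution above about 6 that a 1e-8 round trip
  # is no longer meaningful there.
  mono_range <- list(probit = c(-8, 8), logit = c(-8, 8),
                     loglog = c(-6.5, 8), cloglog = c(-8, 3.5))
  round_range <- list(probit = c(-8, 5.5), logit = c(-8, 8),
                      loglog = c(-6.5, 8), cloglog = c(-8, 3))
  for (nm in c("probit", "logit", "loglog", "cloglog")) {
    lk <- make_link(nm)
    xs <- seq(mono_range[[nm]][1], mono_range[[nm]][2], by = 0.25)
    # strictly increasing CDF with the right limits
    expect_true(all(diff(lk$cdf(xs)) > 0), info = nm)
    expect_lt(lk$cdf(-40), 1e-10)
    expect_gt(lk$cdf(40), 1 - 1e-10)
    # quantile inverts the CDF (absolute error)
    xr <- seq(round_range[[nm]][1], round_range[[nm]][2], by = 0.25)
    expect_lt(max(abs(lk$quantile(lk$cdf(xr)) - xr)), 1e-8)
    # density is the derivative of the CDF
    xs2 <- seq(-6, 6, by = 0.5)
    h <- 1e-6
    fd <- (lk$cdf(xs2 + h) - lk$cdf(xs2 - h)) / (2 * h)
    expect_equal(lk$density(xs2), fd, tolerance = 1e-5, info = nm)
    # log-concave density: log f has nonincreasing finite-difference slope
    # (unimodality is the observable consequence checked here)
    lf <- log(lk$density(seq(-6, 6, by = 0.1)))
    slopes <- diff(lf)
    expect_true(all(diff(slopes) < 1e-8), info = nm)
  }
})

test_that("probit and logit are symmetric; the loglog link is not", {
  xs <- seq(-10, 10, by = 0.5)
  for (nm in c("probit", "logit")) {
    lk <- make_link(nm)
    expect_equal(lk$cdf(-xs), 1 - lk$cdf(xs), tolerance = 1e-12)
  }
  ll <- make_link("loglog")
  expect_gt(abs(ll$cdf(-1) - (1 - ll$cdf(1))), 0.05)
})

test_that("make_link handles known names and rejects unknown ones", {
  expect_equal(make_link("probit")$cdf(0), 0.5)
  expect_equal(make_link("logit")$quantile(0.5), 0)
  expect_equal(make_link("probit")$quantile(0.975), 1.959964, tolerance = 1e-6)
  expect_error(make_link("cauchit"), class = "mwcpm_unsupported_link")
})

test_that("cell probabilities match direct integration of the density", {
  # numerical-integration oracle for a moderate cell
  for (nm in c("probit", "logit", "loglog")) {
    lk <- make_link(nm)
    oracle <- stats::integrate(lk$density, -1, 1, rel.tol = 1e-10)$value
    expect_equal(cell_probability(lk, 1, -1), oracle, tolerance = 1e-8)
  }
  expect_equal(cell_probability(make_link("probit"), 1, -1), 0.682689,
               tolerance = 1e-6)
  expect_equal(cell_probability(make_link("probit"), Inf, -Inf), 1)
})

test_that("sentinel bounds reduce to one-sided probabilities", {
  for (nm in c("probit", "logit", "loglog")) {
    lk <- make_link(nm)
    expect_equal(cell_probability(lk, 1.3, -Inf), lk$cdf(1.3))
    expect_equal(cell_probability(lk, Inf, 0.4), 1 - lk$cdf(0.4),
                 tolerance = 1e-12)
  }
})

test_that("far-tail cells keep relative accuracy and never underflow to zero", {
  # deep-left-tail logit cell: log of the difference has a closed form
  lk <- make_link("logit")
  p <- cell_probability(lk, -30, -31)
  expect_gt(p, 0)
  target <- log(plogis(-30)) + log1p(-plogis(-31) / plogis(-30))
  expect_equal(log(p), target, tolerance = 1e-6)
  # same check mirrored into the right tail (complementary-CDF branch)
  p2 <- cell_probability(lk, 31, 30)
  expect_equal(log(p2), target, tolerance = 1e-6)
  # no exact zeros anywhere in the fitting range
  for (nm in c("probit", "logit", "loglog")) {
    lo <- seq(-40, 39.9, by = 2.5)
    p <- cell_probability(make_link(nm), lo + 1e-6, lo)
    expect_true(all(p > 0), info = nm)
  }
})

test_that("degenerate cell bounds are rejected", {
  lk <- make_link("probit")
  expect_error(cell_probability(lk, -1, 1), class = "mwcpm_ordering_error")
  expect_error(cell_probability(lk, 1, 1), class = "mwcpm_ordering_error")
})
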