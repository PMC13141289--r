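test_that("the likelihood reduces to n log 2 in the symmetric binary case", {
  y <- rep(c(0, 1), each = 10)
  df <- tibble::tibble(y = y, a = rep_len(0:1, 20))
  md <- model_data(df, "y", "a")
  expect_equal(cpm_neg_loglik(alpha = 0, beta = numeric(0), tau = 0,
                              data = md, link = "logit"),
               20 * log(2), tolerance = 1e-12)
})

test_that("neg_loglik matches a brute-force product-of-cells oracle", {
  for (seed in 1:8) {
    for (ties in c(FALSE, TRUE)) {
      dat <- random_tiny_data(n = 5 + seed %% 4, seed = 100 + seed,
                              ties = ties)
      K <- length(unique(dat$y))
      pars <- random_params(K, 1, seed)
      md <- model_data(dat$df, "y", "a", "x")
      for (nm in c("probit", "logit", "loglog")) {
        got <- cpm_neg_loglik(pars$alpha, pars$beta, pars$tau, md, nm)
        want <- oracle_neg_loglik(pars$alpha, pars$beta, pars$tau,
                                  dat$y, dat$x, dat$a, nm)
        expect_equal(got, want, tolerance = 1e-10)
      }
    }
  }
})

test_that("neg_loglik is invariant to monotone transforms and rejects bad alpha", {
  dat <- random_tiny_data(8, seed = 42)
  pars <- random_params(8, 1, 7)
  md1 <- model_data(dat$df, "y", "a", "x")
  md2 <- model_data(dplyr::mutate(dat$df, y = exp(y)), "y", "a", "x")
  expect_equal(
    cpm_neg_loglik(pars$alpha, pars$beta, pars$tau, md1, "probit"),
    cpm_neg_loglik(pars$alpha, pars$beta, pars$tau, md2, "probit"))
  expect_error(
    cpm_neg_loglik(rev(pars$alpha), pars$beta, pars$tau, md1, "probit"),
    class = "mwcpm_ordering_error")
})

test_that("a binary-outcome CPM with logit link is binary logistic regression", {
  set.seed(11)
  n <- 150
  x <- rnorm(n)
  a <- rbinom(n, 1, 0.5)
  y <- rbinom(n, 1, plogis(-0.2 + 0.4 * x + 0.6 * a))
  df <- tibble::tibble(y = y, a = a, x = x)
  fit <- fit_cpm(df, "y", "a", "x", link = "logit")
  ref <- glm(y ~ x + a, family = binomial, data = df)
  expect_equal(unname(fit$beta), unname(coef(ref)["x"]), tolerance = 1e-6)
  expect_equal(fit$tau, unname(coef(ref)["a"]), tolerance = 1e-6)
  expect_equal(fit$alpha, -unname(coef(ref)["(Intercept)"]), tolerance = 1e-6)
})

test_that("the NPMLE recovers the generating coefficients on exact model data", {
  # average over 5 independent datasets so the bound is ~3 Monte Carlo SEs
  fits <- lapply(1:5, function(r) {
    d <- generate_dataset(2000, beta = 0.5, tau = 0.5,
                          seed = child_seed(1, r))
    fit_cpm(d, "y", "a", "x", link = "probit")
  })
  expect_true(all(vapply(fits, `[[`, logical(1), "converged")))
  expect_lt(abs(mean(vapply(fits, function(f) unname(f$beta),
                            numeric(1))) - 0.5), 0.06)
  expect_lt(abs(mean(vapply(fits, `[[`, numeric(1), "tau")) - 0.5), 0.06)
})

test_that("fits are invariant to monotone outcome transformations", {
  d <- generate_dataset(250, beta = 0.5, tau = 0.5, seed = 9)
  f1 <- fit_cpm(d, "y", "a", "x", link = "probit")
  f2 <- fit_cpm(dplyr::mutate(d, y = y^3), "y", "a", "x", link = "probit")
  f3 <- fit_cpm(dplyr::mutate(d, y = log(y)), "y", "a", "x", link = "probit")
  for (f in list(f2, f3)) {
    expect_equal(f$beta, f1$beta, tolerance = 1e-6)
    expect_equal(f$tau, f1$tau, tolerance = 1e-6)
    expect_equal(f$loglik, f1$loglik, tolerance = 1e-6)
    # the intercepts are the same sequence; only their y labels move
    expect_equal(f$alpha, f1$alpha, tolerance = 1e-6)
  }
})

test_that("accepted iterates never decrease the log-likelihood", {
  for (seed in c(2, 13)) {
    d <- generate_dataset(150, beta = 2, tau = 2, seed = seed)
    fit <- fit_cpm(d, "y", "a", "x", link = "probit")
    expect_true(all(diff(fit$loglik_trace) >= -1e-9))
    expect_true(all(diff(fit$alpha) > 0))
  }
})

test_that("stored loglik agrees with direct evaluation at the fitted point", {
  d <- generate_dataset(120, beta = 0.5, tau = 0.5, seed = 5)
  md <- model_data(d, "y", "a", "x")
  for (nm in c("probit", "logit", "loglog")) {
    fit <- fit_cpm(md, link = nm)
    expect_equal(-fit$loglik,
                 cpm_neg_loglik(fit$alpha, fit$beta, fit$tau, md, nm),
                 tolerance = 1e-8)
  }
})

test_that("the intercept block of the Hessian is tridiagonal", {
  dat <- random_tiny_data(7, seed = 77)
  md <- model_data(dat$df, "y", "a", "x")
  fit <- fit_cpm(md, link = "probit")
  K <- fit$K
  h <- 1e-5
  nll <- function(alpha) cpm_neg_loglik(alpha, fit$beta, fit$tau, md, "probit")
  for (j in 1:(K - 3)) {
    for (k in (j + 2):(K - 1)) {
      ej <- ek <- numeric(K - 1)
      ej[j] <- h; ek[k] <- h
      cross <- (nll(fit$alpha + ej + ek) - nll(fit$alpha + ej - ek) -
                nll(fit$alpha - ej + ek) + nll(fit$alpha - ej - ek)) /
               (4 * h^2)
      expect_lt(abs(cross), 1e-4)
    }
  }
})

test_that("conditional CDFs are proper and ordered by the treatment effect", {
  d <- generate_dataset(150, beta = 0.5, tau = 0.5, seed = 21)
  fit <- fit_cpm(d, "y", "a", "x", link = "probit")
  f1 <- conditional_cdf(fit, x = 0.3, a = 1)
  f0 <- conditional_cdf(fit, x = 0.3, a = 0)
  expect_equal(f1$cumprob[fit$K], 1)
  expect_true(all(diff(f1$cumprob) >= 0))
  expect_true(all(f1$cumprob >= 0 & f1$cumprob <= 1))
  expect_gt(fit$tau, 0)
  expect_true(all(f1$cumprob <= f0$cumprob + 1e-12))
  expect_error(conditional_cdf(fit, x = c(1, 2), a = 1),
               class = "mwcpm_shape_error")
})

test_that("conditional CDF values match hand-computed link evaluations", {
  # small fit, then recompute F(y_k | x, a) straight from the definition
  dat <- random_tiny_data(6, seed = 3)
  md <- model_data(dat$df, "y", "a", "x")
  fit <- fit_cpm(md, link = "logit")
  xstar <- 0.7; astar <- 1
  eta <- fit$beta * xstar + fit$tau * astar
  want <- c(plogis(fit$alpha - eta), 1)
  got <- conditional_cdf(fit, xstar, astar)
  expect_equal(got$cumprob, unname(want), tolerance = 1e-12)
})

test_that("too-small samples are rejected", {
  df <- tibble::tibble(y = c(1, 2, 3), a = c(0L, 1L, 0L), x = rnorm(3))
  expect_error(fit_cpm(df, "y", "a", "x"), class = "mwcpm_data_error")
})
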