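test_that("the O(K) Mann-Whitney functional equals the literal double sum", {
  # fixed worked example
  f1 <- new_step_cdf(1:3, cumsum(c(0.2, 0.3, 0.5)))
  f0 <- new_step_cdf(1:3, cumsum(c(0.5, 0.3, 0.2)))
  expect_equal(mw_theta_from_cdfs(f1, f0), 0.695, tolerance = 1e-12)
  # random mass vectors, K up to 20
  for (seed in 1:20) {
    set.seed(seed)
    K <- sample(2:20, 1)
    p1 <- diff(c(0, sort(runif(K - 1)), 1))
    p0 <- diff(c(0, sort(runif(K - 1)), 1))
    s <- sort(rnorm(K))
    got <- mw_theta_from_cdfs(new_step_cdf(s, cumsum(p1)),
                              new_step_cdf(s, cumsum(p0)))
    expect_equal(got, oracle_theta_double_sum(s, p1, p0), tolerance = 1e-12)
  }
})

test_that("equal distributions give 0.5 and extreme point masses give 1", {
  f <- new_step_cdf(c(1, 4, 9), c(0.3, 0.7, 1))
  expect_equal(mw_theta_from_cdfs(f, f), 0.5, tolerance = 1e-12)
  hi <- new_step_cdf(1:3, c(0, 0, 1))
  lo <- new_step_cdf(1:3, c(1, 1, 1))
  expect_equal(mw_theta_from_cdfs(hi, lo), 1)
  expect_error(
    mw_theta_from_cdfs(f, new_step_cdf(c(1, 4, 10), c(0.3, 0.7, 1))),
    class = "mwcpm_grid_mismatch")
})

test_that("the empirical Mann-Whitney probability matches pair enumeration", {
  expect_equal(mw_theta_empirical(c(3, 5), c(1, 3)), 0.875)
  expect_equal(mw_theta_empirical(1:5, 1:5), 0.5)
  expect_equal(mw_theta_empirical(6:8, 1:3), 1)
  expect_error(mw_theta_empirical(numeric(0), 1:3),
               class = "mwcpm_data_error")
  for (seed in 1:10) {
    set.seed(seed)
    y1 <- sample(1:6, 12, replace = TRUE)
    y0 <- sample(1:6, 9, replace = TRUE)
    expect_equal(mw_theta_empirical(y1, y0), oracle_theta_pairs(y1, y0),
                 tolerance = 1e-12)
  }
})

test_that("marginal CDFs by g-computation behave as standardization requires", {
  d <- generate_dataset(150, beta = 0.5, tau = 0.5, seed = 31)
  fit <- fit_cpm(d, "y", "a", "x", link = "probit")
  f1 <- marginal_cdf(fit, 1)
  f0 <- marginal_cdf(fit, 0)
  expect_equal(f1$cumprob[fit$K], 1)
  expect_true(all(diff(f1$cumprob) >= 0))
  expect_true(all(f0$cumprob >= 0 & f0$cumprob <= 1))
  # hand-averaged plug-in values on a tiny fit
  dat <- random_tiny_data(6, seed = 12)
  mdt <- model_data(dat$df, "y", "a", "x")
  ft <- fit_cpm(mdt, link = "probit")
  want <- c(rowMeans(pnorm(outer(ft$alpha, as.numeric(mdt$x %*% ft$beta) +
                                   ft$tau * 1, "-"))), 1)
  expect_equal(marginal_cdf(ft, 1)$cumprob, want, tolerance = 1e-12)
})

test_that("with no covariates the marginal CDF is the link at alpha - tau a", {
  d <- generate_dataset(150, beta = 0, tau = 0.5, seed = 4)
  fit <- fit_cpm(d, "y", "a", covariates = NULL, link = "probit")
  f1 <- marginal_cdf(fit, 1)
  expect_equal(f1$cumprob, c(pnorm(fit$alpha - fit$tau), 1),
               tolerance = 1e-12)
})

test_that("adjusted and unadjusted estimators agree without covariates", {
  # Without covariates the plug-in smooths through the fitted shift model,
  # so it matches the empirical Mann-Whitney probability only up to a
  # root-n model-smoothing term. Generate data from each link's own shift
  # model and average the gap over 5 datasets at n = 1000, where the mean
  # absolute gap sits well below 0.02 for every link.
  for (nm in c("probit", "logit", "loglog")) {
    lk <- make_link(nm)
    gaps <- vapply(1:5, function(r) {
      set.seed(child_seed(6, r))
      eps <- lk$quantile(runif(1000))
      a <- rep_len(c(1L, 0L), 1000)
      df <- tibble::tibble(y = eps + 0.5 * a, a = a)
      emp <- mw_theta_empirical(df$y[a == 1], df$y[a == 0])
      est <- as.numeric(estimate_theta(df, "y", "a", link = nm))
      expect_true(est >= 0 && est <= 1)
      abs(est - emp)
    }, numeric(1))
    expect_lt(mean(gaps), 0.02)
  }
})

test_that("swapping treatment labels reflects the estimate about one half", {
  d <- generate_dataset(200, beta = 0.5, tau = 0.5, seed = 17)
  est <- as.numeric(estimate_theta(d, "y", "a", "x"))
  est_sw <- as.numeric(
    estimate_theta(dplyr::mutate(d, a = 1L - a), "y", "a", "x"))
  expect_equal(est + est_sw, 1, tolerance = 1e-6)
})

test_that("the estimate is invariant to monotone outcome transformations", {
  d <- generate_dataset(200, beta = 0.5, tau = 0.5, seed = 18)
  est <- as.numeric(estimate_theta(d, "y", "a", "x"))
  est_exp <- as.numeric(
    estimate_theta(dplyr::mutate(d, y = exp(y)), "y", "a", "x"))
  expect_equal(est, est_exp, tolerance = 1e-6)
})
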