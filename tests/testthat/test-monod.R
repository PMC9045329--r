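# Monod-family rate laws, parameter extraction and the Gaussian amendment.

test_that("the Monod forms satisfy their defining identities", {
  expect_equal(monod(4e-4, 1.0, 4e-4), 0.5)
  expect_equal(alt_monod(0.625e-3, 1.0, 1600), 0.5)
  expect_equal(monod(0.1, 1.0, 4e-4), 0.9960, tolerance = 1e-4)
  expect_equal(first_order(2e-4, 1600), 0.32)
  expect_equal(liebig(c(1e-4, 1e-2), 1.0, 1600), c(0.16, 1.0))
})

test_that("the alternative form equals Monod when k_m = mu_max/alpha (identity)", {
  C <- 10^seq(-7, 0, length.out = 200)
  mu_max <- 1.3; alpha <- 2100
  expect_equal(alt_monod(C, mu_max, alpha), monod(C, mu_max, mu_max / alpha),
               tolerance = 1e-15)
})

test_that("the control approximations sum to one identically", {
  C <- 10^seq(-6, -1, length.out = 50)
  ac <- approx_control(C, 1.0, 1600)
  expect_equal(ac$eps_MCR + ac$eps_MTA, rep(1, length(C)), tolerance = 1e-15)
  expect_equal(approx_control(0.625e-3, 1.0, 1600)$eps_MCR, 0.5)
  # MTA dominates at vanishing substrate
  expect_gt(approx_control(1e-6, 1.0, 1600)$eps_MTA, 0.99)
})

test_that("extraction recovers the parameters of an exact Monod curve", {
  C <- 10^seq(-6.5, 0, length.out = 240)
  cv <- data.frame(methanol = C, mu = monod(C, 1.0, 4e-4))
  fit <- monod_fit(cv)
  expect_equal(fit$mu_max, 1.0, tolerance = 1e-3)
  expect_equal(fit$k_m, 4e-4, tolerance = 1e-2)
  expect_equal(fit$alpha, 1.0 / 4e-4, tolerance = 1e-2)  # = mu_max / K_M
})

test_that("parameter recovery stays within 1% across generated curves (property)", {
  C <- 10^seq(-7, 0, length.out = 300)
  set.seed(5)
  for (i in 1:5) {
    mu_max <- stats::runif(1, 0.5, 2); km <- 10^stats::runif(1, -3.4, -2.7)
    cv <- data.frame(methanol = C, mu = monod(C, mu_max, km))
    fit <- monod_fit(cv)
    expect_equal(fit$mu_max, mu_max, tolerance = 0.01)
    expect_equal(fit$k_m, km, tolerance = 0.01)
    expect_equal(fit$alpha, mu_max / km, tolerance = 0.01)
  }
})

test_that("a flat curve has no half-saturation point", {
  cv <- data.frame(methanol = 10^seq(-6, 0, 0.1), mu = 1)
  expect_error(extract_k_m(cv, 1), "bracket")
})

test_that("a curve not reaching 1 M cannot provide the maximum rate", {
  cv <- data.frame(methanol = 10^seq(-6, -2, 0.1), mu = 0.5)
  expect_error(extract_mu_max(cv), "1 M")
})

test_that("the amendment peaks at C = mu_max/alpha and decays in both tails", {
  mu <- function(C) amended_monod(C, 1.0, 1600, 0.1, 2.1, 3.1)
  expect_equal(mu(0.625e-3), 0.5 + 0.1)
  expect_equal(mu(1e-8), alt_monod(1e-8, 1.0, 1600), tolerance = 1e-6)
  expect_equal(mu(10), alt_monod(10, 1.0, 1600), tolerance = 1e-3)
  # amended >= alternative everywhere for positive mu_o
  C <- 10^seq(-7, 1, length.out = 100)
  expect_true(all(mu(C) >= alt_monod(C, 1.0, 1600)))
})

test_that("Gaussian amendment fitting recovers constructed parameters to 1%", {
  C <- 10^seq(-6.5, 0, length.out = 400)
  truth <- list(mu_max = 1.0, alpha = 1600, mu_o = 0.1, beta = 2.5)
  cv <- data.frame(methanol = C,
                   mu = amended_monod(C, truth$mu_max, truth$alpha,
                                      truth$mu_o, truth$beta, truth$beta))
  ga <- fit_gaussian_amendment(cv, truth$mu_max, truth$alpha)
  expect_false(ga$degenerate)
  expect_equal(ga$mu_o, 0.1, tolerance = 0.01)
  expect_equal(ga$beta_low, 2.5, tolerance = 0.01)
  expect_equal(ga$beta_high, 2.5, tolerance = 0.01)
})

test_that("an exactly alternative-Monod curve is reported as degenerate", {
  C <- 10^seq(-6, 0, 0.05)
  cv <- data.frame(methanol = C, mu = alt_monod(C, 1.0, 1600))
  ga <- fit_gaussian_amendment(cv, 1.0, 1600)
  expect_equal(ga$mu_o, 0)
  expect_true(ga$degenerate)
})

test_that("rate-law comparison vanishes for self-consistent curves", {
  C <- 10^seq(-6, 0, 0.05)
  cv <- data.frame(methanol = C, mu = monod(C, 1.0, 0.625e-3))
  fit <- monod_fit(cv)
  rl <- rate_law_comparison(cv, fit)
  expect_lt(max(abs(rl$rd_monod)), 0.01)
  # here K_M == mu_max/alpha, so the alternative form agrees too
  expect_lt(max(abs(rl$rd_alt)), 0.01)
})

test_that("monod_fit behaves like a standard fitted-model object", {
  fit <- monod_fit(data.frame(methanol = 10^seq(-6.5, 0, 0.02),
                              mu = monod(10^seq(-6.5, 0, 0.02), 1.0, 4e-4)))
  expect_named(coef(fit), c("mu_max", "k_m", "alpha", "mu_o",
                            "beta_low", "beta_high"))
  expect_output(print(fit), "mu_max")
  expect_length(fitted(fit), length(residuals(fit)))
  expect_equal(predict(fit, 4e-4, type = "monod"), 0.5, tolerance = 1e-3)
  f <- tempfile(fileext = ".json")
  write_monod_report(fit, f)
  expect_equal(jsonlite::read_json(f)$k_m, fit$k_m, tolerance = 1e-12)
})
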