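make_loglog <- function(x, mu) {
  d <- data.frame(x = x, mu = mu, lnx = log(x), lnmu = log(mu))
  class(d) <- c("loglog_dataset", "data.frame")
  d
}

test_that("the age window selects exactly the bins below the boundary", {
  rates <- functional_rate_table(function(x) 1000 / x)
  expect_equal(nrow(build_loglog_dataset(rates, 90)), 25L)
  expect_equal(nrow(build_loglog_dataset(rates, 10)), 9L)
  expect_equal(nrow(build_loglog_dataset(rates, 15)), 10L)
  expect_equal(nrow(build_loglog_dataset(rates, 95)), 26L)
  expect_error(build_loglog_dataset(rates, 12), "boundary")
  # zero-rate bins are excluded
  mu <- 1000 / ((who_age_schema()$A + who_age_schema()$B) / 2)
  mu[3] <- 0
  expect_equal(nrow(build_loglog_dataset(toy_rate_table(mu), 90)), 24L)
  # too few usable points
  mu2 <- rep(0, 26); mu2[1:2] <- 1
  expect_error(build_loglog_dataset(toy_rate_table(mu2), 90), "fewer than 3")
})

test_that("quadratic fit recovers exact coefficients and tests curvature", {
  x <- exp(seq(0, 3, length.out = 8))
  d1 <- make_loglog(x, exp(3 - log(x)))
  q1 <- fit_quadratic(d1)
  expect_equal(unname(q1$coefficients), c(3, -1, 0), tolerance = 1e-8)
  d2 <- make_loglog(x, exp(1 - 2 * log(x) + 0.5 * log(x)^2))
  q2 <- fit_quadratic(d2)
  expect_equal(unname(q2$coefficients), c(1, -2, 0.5), tolerance = 1e-8)
  expect_error(fit_quadratic(make_loglog(c(2, 2, 2, 2), c(1, 2, 3, 4))),
               "collinear|not estimable")
})

test_that("linear fit matches hand least squares and flags the -1 slope", {
  d <- make_loglog(c(1, exp(1), exp(2)), c(exp(2), exp(1), 1))
  f <- fit_linear(d)
  expect_equal(unname(f$coefficients["gamma"]), -1, tolerance = 1e-12)
  expect_equal(unname(f$coefficients["constant"]), 2, tolerance = 1e-12)
  expect_equal(f$r2, 1, tolerance = 1e-12)
  expect_equal(f$mu1, exp(2), tolerance = 1e-10)
  # noisy case: CI from t distribution, adjusted R2 relation
  set.seed(3)
  x <- exp(seq(-2, 3, length.out = 12))
  dn <- make_loglog(x, exp(5 - log(x) + rnorm(12, sd = 0.1)))
  fn <- fit_linear(dn)
  expect_lt(fn$adj_r2, fn$r2)
  expect_true(fn$ci_gamma["lower"] < fn$coefficients["gamma"] &&
                fn$coefficients["gamma"] < fn$ci_gamma["upper"])
  # oracle CI via stats::confint on the same model
  or <- confint(lm(lnmu ~ lnx, dn))[2, ]
  expect_equal(unname(fn$ci_gamma), unname(or), tolerance = 1e-10)
  expect_error(fit_linear(make_loglog(c(2, 2, 2), 1:3)), "slope not estimable")
})

test_that("the inverse-proportion scale estimator has its closed form", {
  d1 <- make_loglog(c(1, 2, 4), 2 / c(1, 2, 4))
  f1 <- fit_inverse(d1)
  expect_equal(f1$lnmu1, log(2), tolerance = 1e-12)
  expect_equal(f1$rb2, 1, tolerance = 1e-12)
  d2 <- make_loglog(c(1, exp(1)), c(exp(1), 1))
  f2 <- fit_inverse(d2)
  expect_equal(f2$lnmu1, 1, tolerance = 1e-12)
  expect_equal(f2$mu1, exp(1), tolerance = 1e-12)
})

test_that("the scale estimator equals the slope-fixed OLS intercept oracle", {
  set.seed(17)
  for (i in 1:100) {
    n <- sample(4:30, 1)
    x <- exp(runif(n, -6, 4))
    mu <- exp(rnorm(n, 2 - log(x), sd = runif(1, 0.01, 1)))
    d <- make_loglog(x, mu)
    ours <- fit_inverse(d)$lnmu1
    # independent route: OLS intercept with the slope fixed at -1
    oracle <- unname(coef(lm(lnmu ~ 1, data = d, offset = -lnx))[1])
    expect_equal(ours, oracle, tolerance = 1e-12)
  }
})

test_that("the two-parameter model never fits worse than the inverse proportion", {
  set.seed(23)
  for (i in 1:50) {
    n <- sample(4:25, 1)
    x <- exp(runif(n, -6, 4))
    mu <- exp(rnorm(n, 1 - 0.8 * log(x), sd = 0.5))
    d <- make_loglog(x, mu)
    expect_gte(fit_linear(d)$r2, fit_inverse(d)$rb2)
    expect_gte(fit_linear(d)$rss * (1 + 1e-12), 0)
    expect_lte(fit_linear(d)$rss, fit_inverse(d)$rss * (1 + 1e-12))
  }
})

test_that("nested F test follows the F(q, n-k) reference distribution", {
  t0 <- nested_f_test(1.5, 1.5, n = 10, k = 2, q = 1)
  expect_equal(t0$statistic, 0)
  expect_equal(t0$p_value, 1)
  t1 <- nested_f_test(2, 1, n = 10, k = 2, q = 1)
  expect_equal(t1$statistic, 8)
  expect_equal(t1$p_value, pf(8, 1, 8, lower.tail = FALSE), tolerance = 1e-12)
  expect_true(t1$reject)
  # fit-object interface agrees with anova() on the same pair of models
  set.seed(5)
  x <- exp(seq(-3, 3, length.out = 15))
  d <- make_loglog(x, exp(2 - log(x) + rnorm(15, sd = 0.3)))
  ours <- nested_f_test(fit_inverse(d), fit_linear(d))
  m0 <- lm(lnmu ~ 1, data = d, offset = -lnx)
  m1 <- lm(lnmu ~ lnx, data = d)
  ref <- anova(m0, m1)
  expect_equal(ours$statistic, ref$F[2], tolerance = 1e-10)
  expect_equal(ours$p_value, ref$`Pr(>F)`[2], tolerance = 1e-10)
  # exact full model under a restricted model that leaves residue
  expect_warning(tz <- nested_f_test(1, 0, n = 10, k = 2, q = 1), "exactly")
  expect_equal(tz$p_value, 0)
})

test_that("residual diagnostics detect planted age structure and pass on none", {
  x <- exp(seq(-3, 3, length.out = 12))
  exact <- make_loglog(x, exp(4 - log(x)))
  dg <- residual_diagnostics(fit_inverse(exact))
  expect_equal(dg$trend$p_value, 1)
  expect_equal(dg$ushape$p_value, 1)
  # planted quadratic signal in the residuals of an inverse fit
  set.seed(9)
  curved <- make_loglog(x, exp(4 - log(x) + 0.3 * log(x)^2 +
                                 rnorm(12, sd = 0.05)))
  dgc <- residual_diagnostics(fit_inverse(curved))
  expect_true(dgc$ushape$reject)
  # planted linear trend
  tilted <- make_loglog(x, exp(4 - 0.5 * log(x) + rnorm(12, sd = 0.05)))
  expect_true(residual_diagnostics(fit_inverse(tilted))$trend$reject)
  expect_message(
    residual_diagnostics(fit_inverse(make_loglog(x[1:3], exp(4 - log(x[1:3]))))),
    "skipped")
})

test_that("slope confidence intervals attain nominal coverage under the model", {
  set.seed(31)
  x <- exp(seq(-5, 2.5, length.out = 12))
  hits <- 0L
  nrep <- 400L
  for (i in seq_len(nrep)) {
    d <- make_loglog(x, exp(3 - log(x) + rnorm(12, sd = 0.2)))
    ci <- fit_linear(d)$ci_gamma
    hits <- hits + (ci["lower"] <= -1 && -1 <= ci["upper"])
  }
  expect_gt(hits / nrep, 0.92)
  expect_lt(hits / nrep, 0.985)
})

test_that("the upper-age sweep reports every window with consistent columns", {
  rates <- functional_rate_table(function(x) 2000 / x)
  sw <- sweep_upper_age(rates)
  expect_equal(sw$upper, seq(5, 90, 5))
  expect_equal(sw$n, c(8, 9, 10:25))
  expect_true(all(abs(sw$gamma + 1) < 1e-10))
  expect_true(all(sw$rb2 > 1 - 1e-10))
  expect_true(all(c("gamma", "ci_lower", "ci_upper", "r2", "adj_r2",
                    "rb2", "f_p", "deaths") %in% names(sw)))
})
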