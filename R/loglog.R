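#' Log-log dataset for trajectory fitting
#'
#' Restricts a rate table to the age window `[0, upper_age)` -- bins whose
#' upper endpoint does not exceed `upper_age` -- keeps bins with a positive
#' rate, and takes natural logarithms of the representative age and the
#' rate.
#'
#' @param rates a `"rate_table"` data frame ([mortality_rates()]).
#' @param upper_age window endpoint in years; must coincide with a bin
#'   boundary of the table.
#' @return A data frame of class `"loglog_dataset"` with columns `x`,
#'   `mu`, `lnx`, `lnmu`; attribute `"upper_age"`.
#' @export
build_loglog_dataset <- function(rates, upper_age) {
  if (!is.numeric(upper_age) || length(upper_age) != 1L || upper_age <= 0)
    stop("'upper_age' must be a single positive age in years")
  if (min(abs(c(rates$A, rates$B) - upper_age)) > 1e-9)
    stop("'upper_age' (", upper_age, ") is not a bin boundary of the rate table")
  keep <- rates$usable & rates$B <= upper_age + 1e-9 &
    is.finite(rates$mu) & rates$mu > 0 & rates$x > 0
  d <- rates[keep, c("x", "mu"), drop = FALSE]
  if (nrow(d) < 3L)
    stop("fewer than 3 usable positive-rate bins below age ", upper_age)
  d$lnx <- log(d$x)
  d$lnmu <- log(d$mu)
  rownames(d) <- NULL
  attr(d, "upper_age") <- upper_age
  class(d) <- c("loglog_dataset", "data.frame")
  d
}

# summary() on exact data warns about perfect fits; exact fits are routine
# in validation work, so that warning alone is muffled
quiet_summary <- function(fit) {
  withCallingHandlers(summary(fit), warning = function(w) {
    if (grepl("essentially perfect fit", conditionMessage(w)))
      invokeRestart("muffleWarning")
  })
}

new_loglog_fit <- function(kind, coefficients, se, rss, r2, n, k, residuals,
                           lnx, extra = list()) {
  out <- c(list(kind = kind, coefficients = coefficients, se = se,
                rss = rss, r2 = r2, n = n, k = k,
                residuals = residuals, lnx = lnx), extra)
  class(out) <- c(paste0("loglog_fit_", kind), "loglog_fit")
  out
}

#' Quadratic log-log fit
#'
#' Ordinary least squares of `ln mu` on `ln x` and `(ln x)^2`.  The Wald
#' t-test of the curvature coefficient against zero is the first rung of
#' the model ladder: curvature indistinguishable from zero licenses the
#' linear log-log model.
#'
#' @param data a `"loglog_dataset"`.
#' @return A `"loglog_fit"` with coefficients `constant`, `gamma`,
#'   `delta`, their standard errors, `rss`, `r2`, residuals and
#'   `p_delta` (two-sided p-value for curvature = 0).
#' @export
fit_quadratic <- function(data) {
  if (nrow(data) < 4L) stop("quadratic fit needs at least 4 points")
  fit <- stats::lm(lnmu ~ lnx + I(lnx^2), data = data)
  if (anyNA(stats::coef(fit)))
    stop("collinear design: the quadratic log-log model is not estimable")
  sm <- quiet_summary(fit)
  cf <- sm$coefficients
  new_loglog_fit(
    "quadratic",
    coefficients = c(constant = unname(cf[1, 1]), gamma = unname(cf[2, 1]),
                     delta = unname(cf[3, 1])),
    se = c(constant = unname(cf[1, 2]), gamma = unname(cf[2, 2]),
           delta = unname(cf[3, 2])),
    rss = sum(stats::resid(fit)^2),
    r2 = sm$r.squared, n = nrow(data), k = 3L,
    residuals = unname(stats::resid(fit)), lnx = data$lnx,
    extra = list(p_delta = unname(cf[3, 4]), p_gamma = unname(cf[2, 4]))
  )
}

#' Linear log-log fit
#'
#' Ordinary least squares of `ln mu` on `ln x`: `ln mu = ln(mu1) + gamma
#' ln x`.  Reports the 95% confidence interval for the slope (t
#' distribution, n - 2 df), the adjusted coefficient of determination for
#' one predictor, and the t-test of the slope against -1, the value at
#' which the trajectory is an exact inverse proportion.
#'
#' @param data a `"loglog_dataset"`.
#' @param level confidence level for the slope interval (default 0.95).
#' @return A `"loglog_fit"` with `coefficients` (`constant` = ln mu1,
#'   `gamma`), `ci_gamma`, `r2`, `adj_r2`, `rss`, `mu1`, and
#'   `p_gamma_m1` (test of gamma = -1).
#' @export
fit_linear <- function(data, level = 0.95) {
  if (nrow(data) < 3L) stop("linear fit needs at least 3 points")
  if (length(unique(data$lnx)) < 2L) stop("all ages equal: slope not estimable")
  fit <- stats::lm(lnmu ~ lnx, data = data)
  sm <- quiet_summary(fit)
  cf <- sm$coefficients
  n <- nrow(data)
  g <- unname(cf[2, 1]); se_g <- unname(cf[2, 2])
  tcrit <- stats::qt(1 - (1 - level) / 2, df = n - 2L)
  t_m1 <- (g - (-1)) / se_g
  new_loglog_fit(
    "linear",
    coefficients = c(constant = unname(cf[1, 1]), gamma = g),
    se = c(constant = unname(cf[1, 2]), gamma = se_g),
    rss = sum(stats::resid(fit)^2),
    r2 = sm$r.squared, n = n, k = 2L,
    residuals = unname(stats::resid(fit)), lnx = data$lnx,
    extra = list(
      adj_r2 = 1 - (1 - sm$r.squared) * (n - 1) / (n - 2),
      ci_gamma = c(lower = g - tcrit * se_g, upper = g + tcrit * se_g),
      level = level,
      mu1 = exp(unname(cf[1, 1])),
      p_gamma_m1 = 2 * stats::pt(abs(t_m1), df = n - 2L, lower.tail = FALSE),
      p_gamma = unname(cf[2, 4])
    )
  )
}

#' Inverse-proportion fit
#'
#' The single-parameter hazard `mu(x) = mu1 / x` is linear on the log-log
#' scale with slope fixed at -1, so its least-squares scale estimator has
#' the closed form `ln(mu1) = mean(ln mu_i + ln x_i)`.  Goodness of fit is
#' summarised by the bespoke coefficient of determination
#' `Rb2 = 1 - SS_resid / SS_total`, with the total sum of squares taken
#' about the mean of `ln mu_i`; `Rb2` can be negative when the model fits
#' worse than a constant.
#'
#' @param data a `"loglog_dataset"`.
#' @return A `"loglog_fit"` with `lnmu1`, `mu1`, `rb2`, `rss` and
#'   residuals.  The `r2` element equals `rb2`.
#' @export
fit_inverse <- function(data) {
  if (nrow(data) < 2L) stop("inverse-proportion fit needs at least 2 points")
  lnmu1 <- mean(data$lnmu + data$lnx)
  res <- data$lnmu - (lnmu1 - data$lnx)
  rss <- sum(res^2)
  sstot <- sum((data$lnmu - mean(data$lnmu))^2)
  rb2 <- 1 - rss / sstot
  new_loglog_fit(
    "inverse",
    coefficients = c(constant = lnmu1, gamma = -1),
    se = c(constant = stats::sd(data$lnmu + data$lnx) / sqrt(nrow(data)),
           gamma = 0),
    rss = rss, r2 = rb2, n = nrow(data), k = 1L,
    residuals = res, lnx = data$lnx,
    extra = list(lnmu1 = lnmu1, mu1 = exp(lnmu1), rb2 = rb2)
  )
}

new_hypothesis_test <- function(statistic, df, p_value, alpha = 0.05,
                                method = "") {
  out <- list(statistic = statistic, df = df, p_value = p_value,
              reject = is.finite(p_value) && p_value < alpha,
              alpha = alpha, method = method)
  class(out) <- "hypothesis_test"
  out
}

#' @export
print.hypothesis_test <- function(x, ...) {
  cat(x$method, ": statistic = ", format(x$statistic, digits = 4),
      ", df = (", paste(x$df, collapse = ", "), "), p = ",
      format(x$p_value, digits = 4),
      if (x$reject) "  [rejected at " else "  [not rejected at ",
      x$alpha, "]\n", sep = "")
  invisible(x)
}

#' Nested model F test
#'
#' Fisher's test comparing the residual sum of squares of a restricted
#' model nested inside a fuller model:
#' `F = ((RSS_r - RSS_f) / q) / (RSS_f / (n - k))` with `q` the number of
#' restricted parameters and `k` the full model's parameter count, referred
#' to the `F(q, n - k)` distribution.
#'
#' @param restricted,full either two `"loglog_fit"` objects fitted to the
#'   same data, or the two residual sums of squares as numbers (then `n`,
#'   `k`, `q` must be given).
#' @param n,k,q sample size, full-model parameter count and number of
#'   restrictions; taken from the fit objects when those are supplied.
#' @return A `"hypothesis_test"` (statistic, df, p-value, 0.05 decision).
#' @export
nested_f_test <- function(restricted, full, n = NULL, k = NULL, q = NULL) {
  if (inherits(restricted, "loglog_fit") && inherits(full, "loglog_fit")) {
    if (restricted$n != full$n)
      stop("the two fits use different numbers of points")
    n <- full$n; k <- full$k; q <- full$k - restricted$k
    rss_r <- restricted$rss; rss_f <- full$rss
  } else {
    rss_r <- restricted; rss_f <- full
    if (is.null(n) || is.null(k) || is.null(q))
      stop("with numeric RSS inputs, 'n', 'k' and 'q' are required")
  }
  if (q < 1L) stop("the restricted model must have fewer parameters")
  if (rss_f > rss_r * (1 + 1e-10) + 1e-12)
    stop("RSS of the full model exceeds that of the restricted model; ",
         "the models are not nested on these data")
  rss_r <- max(rss_r, rss_f)
  if (rss_f == 0) {
    if (rss_r > 0) {
      warning("full model fits exactly (RSS = 0); p-value reported as 0")
      return(new_hypothesis_test(Inf, c(q, n - k), 0, method = "Nested F test"))
    }
    return(new_hypothesis_test(0, c(q, n - k), 1, method = "Nested F test"))
  }
  f <- ((rss_r - rss_f) / q) / (rss_f / (n - k))
  p <- stats::pf(f, q, n - k, lower.tail = FALSE)
  new_hypothesis_test(f, c(q, n - k), p, method = "Nested F test")
}

#' Residual age-independence diagnostics
#'
#' Two regression-based checks that the residuals of a trajectory fit
#' carry no age signal: a t-test of the slope in a regression of the
#' residuals on `ln x` (age trend), and a t-test of the quadratic
#' coefficient in a regression on `ln x` and `(ln x)^2` (U shape).  For
#' fits in which `ln x` was a free regressor the trend test is trivially
#' null; for the slope-fixed inverse-proportion fit it is informative.
#'
#' @param fit a `"loglog_fit"` (residuals and `ln x` design are stored).
#' @return A list of class `"residual_diagnostics"` with elements `trend`
#'   and `ushape` (each a `"hypothesis_test"`); the U-shape test is `NULL`
#'   with a notice when fewer than 4 points are available.
#' @export
residual_diagnostics <- function(fit) {
  if (!inherits(fit, "loglog_fit")) stop("'fit' must be a loglog_fit")
  r <- fit$residuals; u <- fit$lnx
  n <- length(r)
  if (n < 3L) stop("too few residuals for diagnostics")
  trend_fit <- quiet_summary(stats::lm(r ~ u))$coefficients
  trend <- if (nrow(trend_fit) < 2L || !is.finite(trend_fit[2, 4])) {
    # residuals numerically constant: no trend detectable
    new_hypothesis_test(0, c(1, n - 2), 1, method = "Residual age trend (t)")
  } else {
    new_hypothesis_test(trend_fit[2, 3], c(1, n - 2), trend_fit[2, 4],
                        method = "Residual age trend (t)")
  }
  ushape <- NULL
  if (n >= 4L) {
    qfit <- quiet_summary(stats::lm(r ~ u + I(u^2)))$coefficients
    ushape <- if (nrow(qfit) < 3L || !is.finite(qfit[3, 4])) {
      new_hypothesis_test(0, c(1, n - 3), 1, method = "Residual U shape (t)")
    } else {
      new_hypothesis_test(qfit[3, 3], c(1, n - 3), qfit[3, 4],
                          method = "Residual U shape (t)")
    }
  } else {
    message("U-shape test skipped: fewer than 4 residuals")
  }
  out <- list(trend = trend, ushape = ushape)
  class(out) <- "residual_diagnostics"
  out
}

#' @export
print.residual_diagnostics <- function(x, ...) {
  print(x$trend)
  if (!is.null(x$ushape)) print(x$ushape) else cat("U-shape test: skipped\n")
  invisible(x)
}

#' Upper-age sweep of the model ladder
#'
#' Re-fits the linear log-log model and the inverse-proportion model on
#' every window `[0, A)` for `A` in `uppers`, reporting per window the
#' slope with its confidence interval, the plain and adjusted coefficients
#' of determination, the inverse-proportion `Rb2`, the p-value of the
#' nested F test of the linear model against the inverse proportion, and
#' the deaths behind the window.
#'
#' @param rates a `"rate_table"`.
#' @param uppers window endpoints in years (default `seq(5, 90, 5)`).
#' @param level confidence level for the slope intervals.
#' @return A data frame of class `"age_sweep"`, one row per window:
#'   `upper`, `n`, `deaths`, `gamma`, `ci_lower`, `ci_upper`, `r2`,
#'   `adj_r2`, `rb2`, `f_p`.
#' @export
sweep_upper_age <- function(rates, uppers = seq(5, 90, by = 5), level = 0.95) {
  rows <- lapply(uppers, function(a) {
    d <- build_loglog_dataset(rates, a)
    lin <- fit_linear(d, level = level)
    inv <- fit_inverse(d)
    ft <- nested_f_test(inv, lin)
    data.frame(upper = a, n = lin$n,
               deaths = sum(rates$D[rates$usable & rates$B <= a + 1e-9]),
               gamma = unname(lin$coefficients["gamma"]),
               ci_lower = unname(lin$ci_gamma["lower"]),
               ci_upper = unname(lin$ci_gamma["upper"]),
               r2 = lin$r2, adj_r2 = lin$adj_r2, rb2 = inv$rb2,
               f_p = ft$p_value)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("age_sweep", "data.frame")
  out
}

#' @export
print.loglog_fit <- function(x, ...) {
  cat("Log-log ", x$kind, " fit: n = ", x$n, "\n", sep = "")
  cf <- rbind(estimate = x$coefficients, se = x$se)
  print(cf, digits = 5)
  cat("RSS =", format(x$rss, digits = 5), " R2 =", format(x$r2, digits = 5))
  if (!is.null(x$adj_r2)) cat("  adj R2 =", format(x$adj_r2, digits = 5))
  if (!is.null(x$rb2)) cat("  Rb2 =", format(x$rb2, digits = 5))
  cat("\n")
  if (!is.null(x$ci_gamma))
    cat(sprintf("%d%% CI for gamma: (%.4f, %.4f); P(gamma = -1) = %.4g\n",
                round(100 * x$level), x$ci_gamma["lower"], x$ci_gamma["upper"],
                x$p_gamma_m1))
  invisible(x)
}
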