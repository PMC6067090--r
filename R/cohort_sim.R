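#' Simulation configuration for the congenital-risk cohort generator
#'
#' Bundles and validates the parameters of the generative model: each
#' individual is born with a fixed, age-independent risk `r` drawn from a
#' truncated reciprocal (log-uniform) density on `[r_min, r_max]`, lives
#' an exponential lifetime with rate `r` (plus an optional constant
#' background hazard), and is censored at the follow-up horizon.
#'
#' Defaults: one layout cell of `n = 1e6` births (pooling replicates of a
#' cell leaves all rates unchanged, so a multi-cell layout adds nothing
#' statistically), `r_max = 2.9` per year (a bent-regime upper risk
#' limit), `r_min = 1e-4` per year, horizon 95 years matching the last
#' usable WHO age bin.
#'
#' @param n births per layout cell.
#' @param r_min,r_max risk bounds, per year, `0 < r_min < r_max`.
#' @param form `"reciprocal"` (default) or `"point"`; the point form puts
#'   all mass at `r0` and models a homogeneous cohort.
#' @param r0 risk of the point form, per year.
#' @param horizon follow-up in years (censoring age).
#' @param layout data frame with columns `country` and `year`, one row per
#'   emulated country-year cell.
#' @param background optional constant background hazard added to every
#'   individual risk (per year, default 0).
#' @param carrier_fraction fraction of births that carry a congenital
#'   risk at all (default 1).  Values below 1 emulate the rare-cause
#'   setting of real cause-of-death data, where the population
#'   denominator is dominated by individuals who never die of the cause
#'   and therefore barely depletes; non-carriers contribute exposure but
#'   no deaths.
#' @param seed integer seed governing all randomness of the experiment.
#' @param cause three-character ICD-10-style code under which simulated
#'   deaths are tabulated.
#' @return A validated list of class `"simulation_config"`.
#' @export
simulation_config <- function(n = 1e6, r_min = 1e-4, r_max = 2.9,
                              form = c("reciprocal", "point"), r0 = NULL,
                              horizon = 95,
                              layout = data.frame(country = "SIM1",
                                                  year = 2000L),
                              background = 0, carrier_fraction = 1,
                              seed = 1L, cause = "G00") {
  form <- match.arg(form)
  if (!is.numeric(n) || n < 1) stop("'n' must be a positive count")
  if (form == "reciprocal") {
    if (!(r_min > 0 && r_max > r_min))
      stop("need 0 < r_min < r_max for the reciprocal risk density")
  } else if (is.null(r0) || r0 <= 0) {
    stop("point form needs a positive 'r0'")
  }
  if (horizon <= 0) stop("'horizon' must be positive")
  if (!is.data.frame(layout) || !all(c("country", "year") %in% names(layout)) ||
      nrow(layout) < 1L)
    stop("'layout' must be a data frame with columns country, year")
  if (background < 0) stop("'background' hazard cannot be negative")
  if (!is.numeric(carrier_fraction) || carrier_fraction <= 0 ||
      carrier_fraction > 1)
    stop("'carrier_fraction' must be in (0, 1]")
  if (!grepl("^[A-Z][0-9]{2}$", cause))
    stop("'cause' must be a three-character code (letter + two digits)")
  out <- list(n = as.integer(n), r_min = r_min, r_max = r_max, form = form,
              r0 = r0, horizon = horizon, layout = layout,
              background = background, carrier_fraction = carrier_fraction,
              seed = as.integer(seed), cause = cause)
  class(out) <- "simulation_config"
  out
}

#' Sample congenital risks from the truncated reciprocal density
#'
#' Inverse-CDF sampling of `f(r) = c / r` on `[r_min, r_max]`:
#' `r = r_min (r_max / r_min)^U` with `U ~ Uniform(0, 1)`, i.e. `ln r` is
#' uniform on `[ln r_min, ln r_max]`.
#'
#' @param n number of draws.
#' @param r_min,r_max support bounds, `0 < r_min < r_max`.
#' @param seed optional integer; when given, the RNG is seeded first.
#' @return Numeric vector of `n` risks.
#' @export
sample_frailty <- function(n, r_min, r_max, seed = NULL) {
  if (!(is.numeric(r_min) && r_min > 0))
    stop("'r_min' must be > 0: the reciprocal density is non-normalisable at 0")
  if (r_max <= r_min) stop("'r_max' must exceed 'r_min'")
  if (!is.null(seed)) set.seed(seed)
  r_min * (r_max / r_min)^stats::runif(n)
}

#' Simulate exponential lifetimes for a cohort of risks
#'
#' Age-independent individual hazard means exponential lifetime: death
#' age `t_j ~ Exp(rate = r_j)`.  Individuals outliving the horizon are
#' censored (no death age).
#'
#' @param risks positive individual hazards, per year.
#' @param horizon censoring age in years.
#' @param seed optional integer; when given, the RNG is seeded first.
#' @return A data frame of class `"simulated_cohort"` with columns `risk`,
#'   `death_age` (`NA` when censored) and `censored`; attribute
#'   `"horizon"`.
#' @export
simulate_lifetimes <- function(risks, horizon = 95, seed = NULL) {
  if (any(!is.finite(risks)) || any(risks <= 0))
    stop("'risks' must be positive and finite")
  if (!is.null(seed)) set.seed(seed)
  t <- stats::rexp(length(risks), rate = risks)
  cens <- t > horizon
  out <- data.frame(risk = risks,
                    death_age = ifelse(cens, NA_real_, t),
                    censored = cens)
  attr(out, "horizon") <- horizon
  class(out) <- c("simulated_cohort", "data.frame")
  out
}

#' Tabulate a simulated cohort into the WHO file dialect
#'
#' Bins the cohort's death ages into the detailed WHO age schema
#' (populating the four infant columns), sets live births to the cohort
#' size, and derives the population table from survivor counts at each
#' single year of age -- exactly the denominators [halley_pool()]
#' expects, through an independent code path.  Deaths at or beyond age 95
#' go to the terminal 95+ column, which pooling excludes.
#'
#' @param cohort a `"simulated_cohort"`.
#' @param schema the detailed WHO schema ([who_age_schema()]).
#' @param country,year identifiers of the emulated country-year cell.
#' @param cause three-character code under which deaths are reported.
#' @param sex WHO sex code (default 9, unspecified).
#' @param extra_population number of additional never-dying individuals
#'   (risk-free non-carriers) added to the live births and to every
#'   survivor count (default 0).
#' @return A list with elements `deaths` (one-row `"who_deaths"`-shaped
#'   data frame) and `population` (`"who_population"`-shaped data frame,
#'   ages 0--94).
#' @export
tabulate_who <- function(cohort, schema = who_age_schema(),
                         country = "SIM1", year = 2000L,
                         cause = "G00", sex = 9L, extra_population = 0L) {
  if (!is_who_schema(schema))
    stop("'schema' must be the detailed WHO schema to emit WHO-dialect files")
  t <- cohort$death_age[!cohort$censored]
  n <- nrow(cohort) + as.integer(extra_population)
  breaks <- c(schema$A, 95)
  in_bins <- t[t < 95]
  counts <- if (length(in_bins) > 0L) {
    tabulate(findInterval(in_bins, breaks, rightmost.closed = FALSE),
             nbins = nrow(schema))
  } else integer(nrow(schema))
  d95plus <- sum(t >= 95)

  row <- data.frame(Country = country, Admin1 = "", SubDiv = "",
                    Year = as.integer(year), List = "103", Cause = cause,
                    Sex = as.integer(sex), Frmat = 1L, IM_Frmat = 1L,
                    stringsAsFactors = FALSE)
  deaths_cols <- as.list(integer(26))
  names(deaths_cols) <- paste0("Deaths", 1:26)
  deaths_cols$Deaths1 <- length(t)                 # all ages
  deaths_cols$Deaths2 <- sum(counts[1:4])          # age 0
  for (i in 1:4) deaths_cols[[paste0("Deaths", 2 + i)]] <- counts[4 + i]
  for (i in 1:18) deaths_cols[[paste0("Deaths", 6 + i)]] <- counts[8 + i]
  deaths_cols$Deaths25 <- d95plus
  deaths_cols$Deaths26 <- 0L                       # no unknown ages simulated
  im <- as.list(counts[1:4])
  names(im) <- paste0("IM_Deaths", 1:4)
  deaths <- cbind(row, as.data.frame(deaths_cols), as.data.frame(im))
  class(deaths) <- c("who_deaths", "data.frame")

  ages <- 0:94
  survivors <- n - vapply(ages, function(a) sum(t <= a), integer(1L))
  population <- data.frame(Country = country, Year = as.integer(year),
                           Age = ages, Pop = survivors, LiveBirths = n,
                           stringsAsFactors = FALSE)
  class(population) <- c("who_population", "data.frame")

  stopifnot(sum(counts) + d95plus == length(t))    # conservation
  list(deaths = deaths, population = population)
}

#' Simulate a WHO-dialect dataset under a configuration
#'
#' Runs the generative model independently in every layout cell and
#' row-binds the tabulated death and population records.  All randomness
#' flows from `config$seed`.
#'
#' @param config a [simulation_config()].
#' @return A list with `deaths`, `population` and `truth` (the generative
#'   parameters).
#' @export
simulate_who_dataset <- function(config) {
  if (!inherits(config, "simulation_config"))
    stop("'config' must be a simulation_config")
  set.seed(config$seed)
  deaths <- list(); population <- list()
  for (i in seq_len(nrow(config$layout))) {
    n_carrier <- round(config$n * config$carrier_fraction)
    risks <- if (config$form == "reciprocal") {
      sample_frailty(n_carrier, config$r_min, config$r_max)
    } else {
      rep(config$r0, n_carrier)
    }
    risks <- risks + config$background
    n_free <- config$n - n_carrier
    if (config$background > 0 && n_free > 0) {
      # non-carriers still die of the background hazard
      risks <- c(risks, rep(config$background, n_free))
      n_free <- 0L
    }
    cohort <- simulate_lifetimes(risks, horizon = config$horizon)
    tab <- tabulate_who(cohort, country = config$layout$country[i],
                        year = config$layout$year[i], cause = config$cause,
                        extra_population = n_free)
    deaths[[i]] <- tab$deaths
    population[[i]] <- tab$population
  }
  deaths <- do.call(rbind, deaths)
  population <- do.call(rbind, population)
  class(deaths) <- c("who_deaths", "data.frame")
  class(population) <- c("who_population", "data.frame")
  list(deaths = deaths, population = population,
       truth = unclass(config)[c("form", "r_min", "r_max", "r0", "background")])
}

#' Parameter-recovery experiment
#'
#' Closes the loop on the estimators: simulate a cohort under the
#' generative model, tabulate it into the WHO dialect, Halley-pool, build
#' the rate trajectory, and fit the model ladder and the bent curve.
#' Reports the fitted log-log slope with its confidence interval and
#' whether the interval covers -1, the inverse-proportion `Rb2`, and the
#' bent-curve estimates with their relative error against the generative
#' truth.
#'
#' @param config a [simulation_config()].
#' @param window fitting window in years, default `c(0, 10)`.
#' @return A list of class `"recovery_report"`.
#' @export
recovery_experiment <- function(config, window = c(0, 10)) {
  sim <- simulate_who_dataset(config)
  bins <- halley_pool(sim$deaths, sim$population)
  rates <- mortality_rates(bins)
  d <- build_loglog_dataset(rates, window[2])
  lin <- fit_linear(d)
  inv <- fit_inverse(d)
  quad <- fit_quadratic(d)
  tc <- fit_tcir(rates, window = window)
  truth_rmax <- if (config$form == "reciprocal") config$r_max else NA_real_
  out <- list(
    config = config, window = window,
    n_deaths = sum(bins$D),
    gamma_hat = unname(lin$coefficients["gamma"]),
    ci_gamma = lin$ci_gamma,
    covers_minus1 = unname(lin$ci_gamma["lower"] <= -1 &
                             -1 <= lin$ci_gamma["upper"]),
    rb2 = inv$rb2,
    r2_linear = lin$r2,
    delta_hat = unname(quad$coefficients["delta"]),
    p_delta = quad$p_delta,
    tcir_mu1 = tc$mu1,
    tcir_r_max = tc$r_max,
    tcir_r2 = tc$r2,
    r_max_rel_error = if (is.na(truth_rmax)) NA_real_ else
      tc$r_max / truth_rmax - 1,
    rates = rates
  )
  class(out) <- "recovery_report"
  out
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("Recovery experiment (%s risks, n = %d x %d cell(s), seed %d)\n",
              x$config$form, x$config$n, nrow(x$config$layout),
              x$config$seed))
  cat(sprintf("  deaths pooled below 95 y: %d\n", round(x$n_deaths)))
  cat(sprintf("  gamma_hat = %.4f, 95%% CI (%.4f, %.4f), covers -1: %s\n",
              x$gamma_hat, x$ci_gamma["lower"], x$ci_gamma["upper"],
              x$covers_minus1))
  cat(sprintf("  Rb2 (inverse proportion) = %.4f; quadratic delta = %.4f (p = %.3g)\n",
              x$rb2, x$delta_hat, x$p_delta))
  cat(sprintf("  bent curve: mu1 = %.5g, r_max = %.4g (rel. error %s)\n",
              x$tcir_mu1, x$tcir_r_max,
              if (is.na(x$r_max_rel_error)) "n/a" else
                sprintf("%+.1f%%", 100 * x$r_max_rel_error)))
  invisible(x)
}
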