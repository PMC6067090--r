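#' Run the full trajectory pipeline from a configuration
#'
#' Orchestrates the end-to-end analysis: read WHO-dialect death and
#' population files (or simulate them under the congenital-risk
#' generative model), Halley-pool, build the rate trajectory, sweep the
#' upper-age windows of the model ladder, fit the bent curve, summarise
#' per-country-year extreme-age ratios, and (for simulated input) run the
#' parameter-recovery report.  Every intermediate table is written
#' tab-separated to `output_dir` at 6 significant digits; progress is
#' logged to standard error; the run is deterministic given the
#' configuration (including its seed).
#'
#' The configuration is a named list (or a YAML file containing one) with
#' exactly one of
#' \describe{
#'   \item{`deaths`, `population`}{paths to WHO-dialect input files, plus
#'     optional `causes` (specification string, default `"ALL"`),
#'     `countries`, `years`;}
#'   \item{`simulation`}{arguments for [simulation_config()].}
#' }
#' and optional `tcir_window` (default `c(0, 10)`), `uppers` (default
#' `seq(5, 90, 5)`) and `seed`.
#'
#' @param config named list or path to a YAML file.
#' @param output_dir directory for the report tables (created if needed).
#' @return Invisibly, a list with the pooled `rates`, the `sweep`, the
#'   `tcir` fit, the `extremes` rows (real input) or `recovery` report
#'   (simulated input), and the vector of files written.
#' @export
run_pipeline <- function(config, output_dir) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("'config' must be a list or a YAML file path")
  has_real <- !is.null(config$deaths) || !is.null(config$population)
  has_sim <- !is.null(config$simulation)
  if (has_real == has_sim)
    stop("configuration must name exactly one input source: ",
         "either 'deaths' + 'population' paths, or 'simulation'")
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  emit <- function(df, name) {
    path <- file.path(output_dir, name)
    num <- vapply(df, is.numeric, logical(1L))
    df[num] <- lapply(df[num], signif, digits = 6L)
    utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
    files <<- c(files, path)
    path
  }
  stage <- function(name, expr) {
    message("[", name, "] ...")
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  extremes <- NULL; recovery <- NULL; sim <- NULL
  if (has_sim) {
    sim_cfg <- stage("configure", do.call(simulation_config, config$simulation))
    sim <- stage("simulate", simulate_who_dataset(sim_cfg))
    deaths <- sim$deaths; population <- sim$population
  } else {
    if (is.null(config$deaths) || is.null(config$population))
      stop("real input needs both 'deaths' and 'population' paths")
    causes <- if (is.null(config$causes)) "ALL" else config$causes
    deaths <- stage("read deaths",
                    read_who_deaths(config$deaths, causes = causes,
                                    countries = config$countries,
                                    years = config$years))
    population <- stage("read population",
                        read_population(config$population,
                                        countries = config$countries,
                                        years = config$years))
  }

  bins <- stage("pool", halley_pool(deaths, population))
  rates <- stage("rates", mortality_rates(bins))
  emit(as.data.frame(rates), "rate_table.tsv")

  uppers <- if (is.null(config$uppers)) seq(5, 90, by = 5) else config$uppers
  uppers <- uppers[vapply(uppers, function(a)
    sum(rates$usable & rates$B <= a + 1e-9 & rates$mu > 0) >= 3, logical(1L))]
  sweep <- stage("sweep", sweep_upper_age(rates, uppers = uppers))
  emit(as.data.frame(sweep), "model_ladder_sweep.tsv")

  window <- if (is.null(config$tcir_window)) c(0, 10) else config$tcir_window
  tcir <- stage("bent curve", fit_tcir(rates, window = window))
  emit(tcir$data, "tcir_fitted_curve.tsv")
  emit(data.frame(mu1 = tcir$mu1, r_max = tcir$r_max, rss = tcir$rss,
                  r2 = tcir$r2, adj_r2 = tcir$adj_r2, n = tcir$n),
       "tcir_fit.tsv")

  lin <- fit_linear(build_loglog_dataset(rates, window[2]))
  emit(trajectory_table(rates, lin, tcir), "trajectories.tsv")

  if (has_real) {
    extremes <- stage("extremes", {
      cy <- unique(as.data.frame(population)[c("Country", "Year")])
      rows <- lapply(seq_len(nrow(cy)), function(i) {
        d1 <- deaths[deaths$Country == cy$Country[i] &
                       deaths$Year == cy$Year[i], , drop = FALSE]
        p1 <- population[population$Country == cy$Country[i] &
                           population$Year == cy$Year[i], , drop = FALSE]
        r1 <- mortality_rates(halley_pool(d1, p1))
        extreme_rates(r1, country = cy$Country[i], year = cy$Year[i])
      })
      do.call(rbind, rows)
    })
    emit(as.data.frame(extremes), "extremes_report.tsv")
  } else {
    recovery <- stage("recovery",
                      recovery_experiment(sim_cfg, window = window))
    emit(data.frame(
      gamma_hat = recovery$gamma_hat,
      ci_lower = recovery$ci_gamma["lower"],
      ci_upper = recovery$ci_gamma["upper"],
      covers_minus1 = recovery$covers_minus1,
      rb2 = recovery$rb2,
      tcir_mu1 = recovery$tcir_mu1, tcir_r_max = recovery$tcir_r_max,
      r_max_rel_error = recovery$r_max_rel_error,
      n_deaths = recovery$n_deaths), "recovery_report.tsv")
  }

  message("[done] ", length(files), " table(s) written to ", output_dir)
  invisible(list(rates = rates, sweep = sweep, tcir = tcir,
                 extremes = extremes, recovery = recovery, files = files))
}

#' Plot-ready log-log trajectory table
#'
#' Assembles observed rates, fitted curves and the two reference
#' straight lines of slope -1 and -2 (anchored at the first observed
#' point) into one table for log-log plotting.
#'
#' @param rates a `"rate_table"`.
#' @param fit a linear `"loglog_fit"` (fitted values `mu1 * x^gamma`);
#'   optional.
#' @param tcir a `"tcir_fit"`; optional.
#' @return Data frame with columns `x`, `mu`, `fit_loglog`, `fit_tcir`,
#'   `ref_slope_m1`, `ref_slope_m2` (unavailable entries `NA`).
#' @export
trajectory_table <- function(rates, fit = NULL, tcir = NULL) {
  obs <- rates[rates$usable & is.finite(rates$mu) & rates$mu > 0, , drop = FALSE]
  if (nrow(obs) == 0L) stop("no usable observed rates")
  x <- obs$x; mu <- obs$mu
  out <- data.frame(x = x, mu = mu)
  out$fit_loglog <- if (!is.null(fit)) {
    fit$mu1 * x^unname(fit$coefficients["gamma"])
  } else NA_real_
  out$fit_tcir <- if (!is.null(tcir)) tcir_hazard(x, tcir$mu1, tcir$r_max)
  else NA_real_
  out$ref_slope_m1 <- mu[1L] * (x / x[1L])^(-1)
  out$ref_slope_m2 <- mu[1L] * (x / x[1L])^(-2)
  out
}
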