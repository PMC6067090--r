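#' Extreme-age mortality rates and their ratios for one country-year
#'
#' Summarises a single country-year rate trajectory by its three extreme
#' values: the first-day rate (bin `[0,1)` day), the lifetime minimum over
#' all bins in `[0, 95)` with the representative age `M` at which it
#' occurs, and the old-age rate (bin `[90,95)` years).  Ratio A is the
#' first-day rate over the minimum; Ratio B is the old-age rate over the
#' minimum.  Rates are reported per 1e5 living persons per year.
#'
#' @param rates a `"rate_table"` for one country-year (internal scale per
#'   1e7).
#' @param country,year optional identifiers carried into the row.
#' @return A one-row data frame of class `"extreme_row"`: `country`,
#'   `year`, `first_day_rate`, `min_rate`, `M`, `old_rate`, `ratio_a`,
#'   `ratio_b`, `incomplete`.
#' @export
extreme_rates <- function(rates, country = NA_character_, year = NA_integer_) {
  scale_in <- attr(rates, "scale")
  if (is.null(scale_in)) scale_in <- 1e7
  per1e5 <- rates$mu / scale_in * 1e5
  ok <- rates$usable & is.finite(per1e5)
  if (!any(ok)) stop("no usable bins in the rate table")
  first_idx <- which(abs(rates$A) < 1e-12)
  old_idx <- which(abs(rates$A - 90) < 1e-9 & abs(rates$B - 95) < 1e-9)
  incomplete <- length(old_idx) == 0L || !ok[old_idx[1L]] ||
    length(first_idx) == 0L || !ok[first_idx[1L]]
  min_idx <- which(ok)[which.min(per1e5[ok])]
  min_rate <- per1e5[min_idx]
  first_day <- if (length(first_idx) > 0L && ok[first_idx[1L]])
    per1e5[first_idx[1L]] else NA_real_
  old_rate <- if (length(old_idx) > 0L && ok[old_idx[1L]])
    per1e5[old_idx[1L]] else NA_real_
  out <- data.frame(
    country = country, year = year,
    first_day_rate = first_day, min_rate = min_rate,
    M = rates$x[min_idx], old_rate = old_rate,
    ratio_a = first_day / min_rate, ratio_b = old_rate / min_rate,
    incomplete = incomplete, stringsAsFactors = FALSE
  )
  class(out) <- c("extreme_row", "data.frame")
  out
}

#' Distributional summary and comparison of the extreme-age ratios
#'
#' Computes means and sample standard deviations of Ratio A (first-day /
#' minimum) and Ratio B (old-age / minimum) over country-years, checks
#' each ratio set for approximate normality, and compares the means with
#' a one-sided paired t-test of the hypothesis that Ratio B is smaller
#' than Ratio A (pairs share a country-year).
#'
#' The default normality check is a one-sample Kolmogorov-Smirnov test of
#' the moment-standardised values against the standard normal.  With
#' parameters estimated from the data this test is conservative, which is
#' exactly the sense in which such ratio sets are usually reported as
#' "approximately normal"; the stricter Shapiro-Wilk test is also
#' computed and reported alongside.
#'
#' @param ratio_a,ratio_b numeric vectors of the two ratios, paired by
#'   country-year; alternatively `ratio_a` may be a data frame of
#'   [extreme_rates()] rows with columns `ratio_a`, `ratio_b`.
#' @param normality which test drives the reported normality p-values:
#'   `"ks"` (default) or `"shapiro"`.
#' @return A list of class `"ratio_summary"`: `n`, `mean_a`, `sd_a`,
#'   `mean_b`, `sd_b`, `normality_p_a`, `normality_p_b` (the chosen
#'   test), `shapiro_p_a`, `shapiro_p_b`, `ks_p_a`, `ks_p_b`, and
#'   `comparison_p` (one-sided paired t, mean B < mean A).  With fewer
#'   than 3 pairs the tests are skipped (`NA`).
#' @export
ratio_summary <- function(ratio_a, ratio_b = NULL,
                          normality = c("ks", "shapiro")) {
  normality <- match.arg(normality)
  if (is.data.frame(ratio_a)) {
    if (!all(c("ratio_a", "ratio_b") %in% names(ratio_a)))
      stop("data frame input needs columns 'ratio_a' and 'ratio_b'")
    ratio_b <- ratio_a$ratio_b
    ratio_a <- ratio_a$ratio_a
  }
  if (length(ratio_a) != length(ratio_b))
    stop("'ratio_a' and 'ratio_b' must be paired (equal length)")
  keep <- is.finite(ratio_a) & is.finite(ratio_b)
  a <- ratio_a[keep]; b <- ratio_b[keep]
  n <- length(a)
  if (n < 1L) stop("no complete ratio pairs")
  ks_p <- function(x) {
    if (stats::sd(x) == 0) return(NA_real_)
    suppressWarnings(
      stats::ks.test((x - mean(x)) / stats::sd(x), "pnorm")$p.value)
  }
  sw_p <- function(x) {
    if (stats::sd(x) == 0) return(NA_real_)
    stats::shapiro.test(x)$p.value
  }
  tests_ok <- n >= 3L
  out <- list(
    n = n,
    mean_a = mean(a), sd_a = stats::sd(a),
    mean_b = mean(b), sd_b = stats::sd(b),
    ks_p_a = if (tests_ok) ks_p(a) else NA_real_,
    ks_p_b = if (tests_ok) ks_p(b) else NA_real_,
    shapiro_p_a = if (tests_ok) sw_p(a) else NA_real_,
    shapiro_p_b = if (tests_ok) sw_p(b) else NA_real_,
    comparison_p = if (!tests_ok) NA_real_ else if (stats::sd(a - b) == 0) {
      # degenerate: all pairwise differences identical
      if (mean(a - b) == 0) 0.5 else if (mean(a - b) > 0) 0 else 1
    } else {
      stats::t.test(a, b, paired = TRUE, alternative = "greater")$p.value
    },
    normality = normality
  )
  out$normality_p_a <- if (normality == "ks") out$ks_p_a else out$shapiro_p_a
  out$normality_p_b <- if (normality == "ks") out$ks_p_b else out$shapiro_p_b
  class(out) <- "ratio_summary"
  out
}

#' @export
print.ratio_summary <- function(x, ...) {
  cat(sprintf("Extreme-age ratio summary over %d country-years\n", x$n))
  cat(sprintf("  Ratio A (first day / minimum): mean %.0f, SD %.0f\n",
              x$mean_a, x$sd_a))
  cat(sprintf("  Ratio B ([90,95) / minimum):   mean %.0f, SD %.0f\n",
              x$mean_b, x$sd_b))
  cat(sprintf("  normality (%s): p_A = %.3g, p_B = %.3g\n",
              x$normality, x$normality_p_a, x$normality_p_b))
  cat(sprintf("  one-sided paired t (mean B < mean A): p = %.3g\n",
              x$comparison_p))
  invisible(x)
}

#' Reference extreme-age rates for nine European countries
#'
#' The bundled reference table of all-cause mortality rates (per 1e5
#' living persons per year) in the three extreme age categories -- first
#' day of life, lifetime minimum, and `[90, 95)` years -- for nine
#' European countries in the first and last ICD-10 calendar years with
#' detailed infant reporting, together with the published Ratio A and
#' Ratio B values.
#'
#' @return Data frame with columns `country`, `year`, `first_day`,
#'   `min_rate`, `M`, `old_rate`, `population`, `ratio_a`, `ratio_b`.
#' @export
eu9_extreme_reference <- function() {
  path <- system.file("extdata", "eu9_extreme_rates.tsv",
                      package = "halleymort", mustWork = TRUE)
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}
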