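#' Age interval schema
#'
#' An age schema is an ordered set of contiguous half-open age intervals
#' \eqn{[A_i, B_i)} in years, starting at exact age 0.  All pooling and rate
#' construction in the package is expressed against such a schema.
#'
#' @param breaks numeric vector of interval boundaries in years, strictly
#'   increasing, starting at 0.  Interval `i` is `[breaks[i], breaks[i+1])`.
#' @return A data frame of class `"age_schema"` with columns `A`, `B`,
#'   `width` (years) and `label`.
#' @seealso [who_age_schema()] for the default WHO schema with detailed
#'   infant intervals.
#' @export
age_schema <- function(breaks) {
  if (!is.numeric(breaks) || length(breaks) < 2L)
    stop("'breaks' must be a numeric vector with at least two boundaries")
  if (anyNA(breaks) || is.unsorted(breaks, strictly = TRUE))
    stop("'breaks' must be strictly increasing with no missing values")
  if (breaks[1L] != 0)
    stop("the first age boundary must be exact age 0")
  A <- breaks[-length(breaks)]
  B <- breaks[-1L]
  out <- data.frame(
    A = A, B = B, width = B - A,
    label = sprintf("[%g,%g)", A, B),
    stringsAsFactors = FALSE
  )
  class(out) <- c("age_schema", "data.frame")
  out
}

#' Default WHO age schema with detailed infant intervals
#'
#' The 26 contiguous intervals used by the WHO Mortality Database when the
#' detailed infant breakdown is reported: `[0,1)`, `[1,7)`, `[7,28)` and
#' `[28,365)` days, single-year intervals `[1,2)` to `[4,5)`, then 5-year
#' intervals `[5,10)` to `[90,95)`.  Days are converted to years with a
#' 365-day year, matching the 1/7/28/365-day interval boundaries.
#'
#' @return An [age_schema()] with 26 intervals covering `[0, 95)` years.
#' @export
who_age_schema <- function() {
  age_schema(c(0, 1 / 365, 7 / 365, 28 / 365, 1:5, seq(10, 95, by = 5)))
}

#' Representative age of an interval
#'
#' The representative age of an age interval is the arithmetic mean of its
#' endpoints; it is the abscissa at which the interval's pooled rate is
#' plotted and fitted.
#'
#' @param A,B interval endpoints in years (vectorised), `A < B`.
#' @return Numeric vector `(A + B) / 2`.
#' @examples
#' representative_age(5, 10)        # 7.5
#' representative_age(0, 1 / 365)   # half a day, in years
#' @export
representative_age <- function(A, B) {
  if (any(!is.finite(A)) || any(!is.finite(B)) || any(B <= A))
    stop("intervals must be finite with A < B")
  (A + B) / 2
}

#' @export
print.age_schema <- function(x, ...) {
  cat("Age schema:", nrow(x), "intervals covering [0,", max(x$B), ") years\n")
  print.data.frame(x, ...)
  invisible(x)
}

# internal: check a schema is the detailed WHO schema (needed to map the
# fixed WHO file columns onto bins)
is_who_schema <- function(schema) {
  ref <- who_age_schema()
  nrow(schema) == nrow(ref) &&
    max(abs(schema$A - ref$A)) < 1e-12 &&
    max(abs(schema$B - ref$B)) < 1e-12
}
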