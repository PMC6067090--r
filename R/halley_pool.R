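#' Map a WHO death record onto the detailed age schema
#'
#' Distributes the death counts of WHO-dialect records over the 26 bins of
#' the detailed schema: the four infant columns feed the four sub-year
#' bins, the single-year columns feed `[1,2)` ... `[4,5)`, and the 5-year
#' columns feed `[5,10)` ... `[90,95)`.  Deaths at 95+ and deaths of
#' unknown age fall outside the schema and are excluded.
#'
#' @param records a `"who_deaths"` data frame (one or more rows).
#' @param schema the age schema; must be the detailed WHO schema
#'   ([who_age_schema()]), since the file columns are fixed.
#' @return A numeric matrix with one row per record and one column per
#'   schema bin.
#' @export
map_raw_ages <- function(records, schema = who_age_schema()) {
  if (!is_who_schema(schema))
    stop("'schema' does not match the WHO detailed age schema; ",
         "the WHO file columns only map onto who_age_schema()")
  cols <- c(paste0("IM_Deaths", 1:4),           # [0,1), [1,7), [7,28), [28,365) days
            paste0("Deaths", 3:6),              # [1,2) ... [4,5) years
            paste0("Deaths", 7:24))             # [5,10) ... [90,95) years
  if (!all(cols %in% names(records)))
    stop("'records' lacks the WHO dialect age columns")
  m <- as.matrix(as.data.frame(records)[cols])
  storage.mode(m) <- "double"
  colnames(m) <- schema$label
  m
}

#' Survivor-depleted population for the sub-year age bins
#'
#' Within the first year of life the number of living persons entering
#' each sub-year interval is taken as the live births minus the deaths in
#' the preceding sub-year intervals (survivor depletion).
#'
#' @param births live births of the country-year (> 0).
#' @param infant_deaths numeric vector of 4 death counts for the intervals
#'   `[0,1)`, `[1,7)`, `[7,28)`, `[28,365)` days.
#' @return Numeric vector of 4 entrant counts.
#' @examples
#' infant_entrants(1000, c(10, 5, 3, 2))  # 1000 990 985 982
#' @export
infant_entrants <- function(births, infant_deaths) {
  if (!is.numeric(births) || length(births) != 1L || births <= 0)
    stop("'births' must be a single positive count")
  if (length(infant_deaths) != 4L || any(infant_deaths < 0))
    stop("'infant_deaths' must be 4 non-negative counts")
  L <- births - cumsum(c(0, infant_deaths[1:3]))
  if (any(L <= 0) || sum(infant_deaths) > births)
    stop("cumulative infant deaths exceed live births (", births, ")")
  L
}

#' Halley pooling of deaths and populations
#'
#' Builds the "large population" by summing, bin by bin, the deaths and
#' the living persons at bin entry over every country and calendar year
#' supplied.  For bins of one year and wider, the living persons `L_i` at
#' the bin's entry age are taken from the single-year population table;
#' for the four sub-year bins they are derived from live births by
#' survivor depletion ([infant_entrants()]) using the infant deaths of the
#' records being pooled.  Person-years are `L_i * (B_i - A_i)`.
#'
#' Country-years present in the population table but absent from the death
#' records contribute exposure with zero deaths, which is what makes the
#' pooled trajectory usable for rare causes.  A country-year with deaths
#' but no population is an error.
#'
#' @param deaths a `"who_deaths"` data frame (see [read_who_deaths()]).
#' @param population a `"who_population"` data frame ([read_population()]).
#' @param schema the age schema (default [who_age_schema()]).
#' @return A data frame of class `"age_bin_counts"` with columns `A`, `B`,
#'   `width`, `label`, `D` (pooled deaths), `L` (pooled entrants) and `PY`
#'   (person-years).
#' @export
halley_pool <- function(deaths, population, schema = who_age_schema()) {
  if (!is_who_schema(schema))
    stop("'schema' must be the detailed WHO schema for WHO-dialect input")
  pop_cy <- unique(paste(population$Country, population$Year))
  if (nrow(deaths) > 0L) {
    death_cy <- unique(paste(deaths$Country, deaths$Year))
    missing <- setdiff(death_cy, pop_cy)
    if (length(missing) > 0L)
      stop("population missing for country-year(s) with deaths: ",
           paste(missing, collapse = "; "))
  }

  nb <- nrow(schema)
  D <- numeric(nb)
  if (nrow(deaths) > 0L)
    D <- colSums(map_raw_ages(deaths, schema))

  # pooled entrants L_i, accumulated country-year by country-year
  L <- numeric(nb)
  entry_ages <- schema$A[schema$width >= 1]        # 1,2,3,4,5,10,...,90
  cy <- unique(as.data.frame(population)[c("Country", "Year")])
  for (i in seq_len(nrow(cy))) {
    sub <- population[population$Country == cy$Country[i] &
                        population$Year == cy$Year[i], ]
    births <- sub$LiveBirths[1L]
    if (nrow(deaths) > 0L) {
      drec <- deaths[deaths$Country == cy$Country[i] & deaths$Year == cy$Year[i], ,
                     drop = FALSE]
    } else {
      drec <- deaths
    }
    inf <- if (nrow(drec) > 0L) {
      c(sum(drec$IM_Deaths1), sum(drec$IM_Deaths2),
        sum(drec$IM_Deaths3), sum(drec$IM_Deaths4))
    } else c(0, 0, 0, 0)
    L[1:4] <- L[1:4] + infant_entrants(births, inf)
    idx <- match(entry_ages, sub$Age)
    L[5:nb] <- L[5:nb] + sub$Pop[idx]
  }

  out <- data.frame(A = schema$A, B = schema$B, width = schema$width,
                    label = schema$label, D = D, L = L, PY = L * schema$width,
                    stringsAsFactors = FALSE)
  total_mapped <- sum(D)
  stopifnot(isTRUE(all.equal(sum(out$D), total_mapped)))  # conservation
  class(out) <- c("age_bin_counts", "data.frame")
  out
}

#' Age-specific mortality rates from pooled bin counts
#'
#' The force of mortality in each bin is estimated as deaths per
#' person-year, `mu_i = D_i / (L_i (B_i - A_i))`, expressed per `scale`
#' living persons per year (default 1e7), at the representative age
#' `x_i = (A_i + B_i) / 2`.  Bins with no exposure are flagged unusable
#' rather than dropped.
#'
#' @param bins an `"age_bin_counts"` data frame from [halley_pool()] (or
#'   any data frame with columns `A`, `B`, `width`, `D`, `L`, `PY`).
#' @param scale rate denominator (living persons), default `1e7`.
#' @return A data frame of class `"rate_table"` with columns `A`, `B`,
#'   `x`, `D`, `L`, `PY`, `mu` and `usable`.
#' @export
mortality_rates <- function(bins, scale = 1e7) {
  need <- c("A", "B", "width", "D", "L", "PY")
  if (!all(need %in% names(bins)))
    stop("'bins' must have columns ", paste(need, collapse = ", "))
  usable <- is.finite(bins$PY) & bins$PY > 0
  mu <- ifelse(usable, bins$D / bins$PY * scale, NA_real_)
  out <- data.frame(A = bins$A, B = bins$B,
                    x = representative_age(bins$A, bins$B),
                    D = bins$D, L = bins$L, PY = bins$PY,
                    mu = mu, usable = usable, stringsAsFactors = FALSE)
  attr(out, "scale") <- scale
  class(out) <- c("rate_table", "data.frame")
  out
}

#' @export
print.rate_table <- function(x, digits = 6, ...) {
  cat("Age-specific mortality rates (per ", format(attr(x, "scale")),
      " person-years), ", nrow(x), " bins\n", sep = "")
  print.data.frame(format(as.data.frame(x), digits = digits), ...)
  invisible(x)
}

#' Write / read the tab-separated rate table
#'
#' The rate table is the interchange format between the pooling stage and
#' all fitting modules.
#'
#' @param rates a `"rate_table"` data frame.
#' @param file path of the tab-separated file.
#' @return `write_rate_table()` returns `file` invisibly;
#'   `read_rate_table()` returns the `"rate_table"` data frame.
#' @export
write_rate_table <- function(rates, file) {
  utils::write.table(as.data.frame(rates), file, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_rate_table
#' @export
read_rate_table <- function(file) {
  df <- utils::read.delim(file, check.names = FALSE)
  class(df) <- c("rate_table", "data.frame")
  attr(df, "scale") <- 1e7
  df
}

#' Cause-subcategory proportions by age bin
#'
#' For cause-resolved pooled deaths, computes the percentage of each cause
#' within each age bin and within the all-age total.  Bins with no deaths
#' have undefined proportions, reported as `NA`.
#'
#' @param deaths a `"who_deaths"` data frame with the `Cause` column
#'   resolved (three-character codes).
#' @param schema the age schema (default [who_age_schema()]).
#' @return A list of class `"cause_proportions"` with elements `by_bin`
#'   (long data frame: `label`, `cause`, `deaths`, `pct`) and `overall`
#'   (`cause`, `deaths`, `pct`).
#' @export
cause_proportions <- function(deaths, schema = who_age_schema()) {
  if (nrow(deaths) == 0L) stop("no death records supplied")
  m <- map_raw_ages(deaths, schema)
  causes <- sort(unique(deaths$Cause))
  counts <- vapply(causes, function(cz)
    colSums(m[deaths$Cause == cz, , drop = FALSE]), numeric(nrow(schema)))
  # counts: bins x causes
  bin_tot <- rowSums(counts)
  pct <- counts / ifelse(bin_tot > 0, bin_tot, NA_real_) * 100
  by_bin <- data.frame(
    label = rep(schema$label, times = length(causes)),
    cause = rep(causes, each = nrow(schema)),
    deaths = as.vector(counts),
    pct = as.vector(pct),
    stringsAsFactors = FALSE
  )
  all_tot <- colSums(counts)
  overall <- data.frame(cause = causes, deaths = as.vector(all_tot),
                        pct = as.vector(all_tot / sum(all_tot) * 100),
                        stringsAsFactors = FALSE)
  out <- list(by_bin = by_bin, overall = overall)
  class(out) <- "cause_proportions"
  out
}

#' @export
print.cause_proportions <- function(x, ...) {
  cat("Cause proportions:", nrow(x$overall), "causes,",
      sum(x$overall$deaths), "deaths\n")
  print.data.frame(x$overall, ...)
  invisible(x)
}
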