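#' @title WHO mortality flat-file dialect
#' @description Column layout of the ICD-10 era WHO Mortality Database
#'   death files as handled by this package: identification and format
#'   columns, 26 age-group death columns (`Deaths1` = all ages, `Deaths2` =
#'   age 0, `Deaths3`--`Deaths6` = single years 1--4, `Deaths7`--`Deaths25` =
#'   5-year groups 5--9 ... 95+, `Deaths26` = age unknown) and the four
#'   detailed infant columns `IM_Deaths1`--`IM_Deaths4` ( `[0,1)`, `[1,7)`,
#'   `[7,28)`, `[28,365)` days).  Only rows whose format codes signal the
#'   detailed breakdown (`Frmat == 1`, `IM_Frmat == 1`) are usable for
#'   trajectory construction.
#' @name who_dialect
NULL

who_death_columns <- function() {
  c("Country", "Admin1", "SubDiv", "Year", "List", "Cause", "Sex",
    "Frmat", "IM_Frmat", paste0("Deaths", 1:26), paste0("IM_Deaths", 1:4))
}

who_population_columns <- function() {
  c("Country", "Year", "Age", "Pop", "LiveBirths")
}

#' ICD-10 cause sets
#'
#' Expand a textual ICD-10 specification into a set of three-character
#' codes.  The specification may be a single code (`"Q05"`), an inclusive
#' hyphenated range with a common letter prefix (`"Q00-Q07"`), a
#' comma-separated list of either, or the special value `"ALL"` meaning no
#' cause filtering.
#'
#' @param spec character scalar as described above.
#' @param name label for the set; defaults to the specification text.
#' @return An object of class `"cause_set"`: a list with elements `name`
#'   and `codes` (sorted unique character vector; empty for `"ALL"`).
#' @examples
#' parse_cause_range("Q00-Q07")  # the 8 congenital CNS anomaly codes
#' parse_cause_range("G00-G99")  # diseases of the nervous system, 100 codes
#' @export
parse_cause_range <- function(spec, name = spec) {
  if (!is.character(spec) || length(spec) != 1L || is.na(spec) || !nzchar(spec))
    stop("'spec' must be a single non-empty character string")
  if (toupper(trimws(spec)) == "ALL") {
    out <- list(name = "ALL", codes = character(0))
    class(out) <- "cause_set"
    return(out)
  }
  tokens <- trimws(strsplit(spec, ",", fixed = TRUE)[[1L]])
  if (any(!nzchar(tokens))) stop("empty token in cause specification '", spec, "'")
  code_re <- "^[A-Z][0-9]{2}$"
  codes <- character(0)
  for (tok in tokens) {
    if (grepl(code_re, tok)) {
      codes <- c(codes, tok)
    } else if (grepl("^[A-Z][0-9]{2}-[A-Z][0-9]{2}$", tok)) {
      lo <- sub("-.*$", "", tok)
      hi <- sub("^.*-", "", tok)
      if (substr(lo, 1, 1) != substr(hi, 1, 1))
        stop("range '", tok, "' mixes letter prefixes")
      lo_n <- as.integer(substr(lo, 2, 3))
      hi_n <- as.integer(substr(hi, 2, 3))
      if (lo_n > hi_n)
        stop("reversed range '", tok, "': start exceeds end")
      codes <- c(codes, sprintf("%s%02d", substr(lo, 1, 1), lo_n:hi_n))
    } else {
      stop("malformed ICD-10 code or range: '", tok, "'")
    }
  }
  out <- list(name = name, codes = sort(unique(codes)))
  class(out) <- "cause_set"
  out
}

#' @export
print.cause_set <- function(x, ...) {
  if (length(x$codes) == 0L) {
    cat("Cause set 'ALL' (no filtering)\n")
  } else {
    cat("Cause set '", x$name, "': ", length(x$codes), " codes (",
        x$codes[1L], "..", x$codes[length(x$codes)], ")\n", sep = "")
  }
  invisible(x)
}

as_cause_set <- function(causes) {
  if (inherits(causes, "cause_set")) return(causes)
  if (is.character(causes) && length(causes) == 1L) return(parse_cause_range(causes))
  stop("'causes' must be a cause_set or a cause specification string")
}

check_counts <- function(df, cols, file, what) {
  m <- as.matrix(df[cols])
  bad <- which(!is.finite(m) | m < 0 | m != round(m), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop("malformed ", what, " in '", file, "' at data row ",
         bad[1L, 1L], ", column ", cols[bad[1L, 2L]],
         ": counts must be non-negative integers")
  }
  invisible(TRUE)
}

#' Read WHO-dialect death records
#'
#' Reads a comma-delimited death file in the WHO ICD-10 dialect (see
#' [who_dialect]), filters to the requested causes, countries and years,
#' and reports four-character causes under their three-character prefix.
#' Rows whose format codes lack the detailed infant breakdown cannot be
#' used for trajectory construction; they are dropped with a warning and
#' returned in the `"unusable"` attribute.
#'
#' @param file path to the delimited text file (header row required).
#' @param causes a [parse_cause_range()] result or specification string;
#'   `"ALL"` (default) keeps every cause.
#' @param countries optional vector of country identifiers to keep.
#' @param years optional integer vector (or range) of calendar years to keep.
#' @return A data frame of class `"who_deaths"` in the dialect's column
#'   layout, with `Cause` collapsed to three characters.  Attribute
#'   `"unusable"` holds rows excluded for lacking infant detail.
#' @export
read_who_deaths <- function(file, causes = "ALL", countries = NULL, years = NULL) {
  causes <- as_cause_set(causes)
  df <- utils::read.csv(file, header = TRUE, colClasses = "character",
                        check.names = FALSE, strip.white = TRUE)
  expected <- who_death_columns()
  if (!identical(names(df), expected))
    stop("'", file, "' does not match the WHO death-file dialect; expected columns: ",
         paste(expected, collapse = ", "))
  count_cols <- c(paste0("Deaths", 1:26), paste0("IM_Deaths", 1:4))
  if (nrow(df) == 0L) {
    df[count_cols] <- lapply(df[count_cols], as.integer)
    df$Year <- integer(0); df$Sex <- integer(0)
    df$Frmat <- integer(0); df$IM_Frmat <- integer(0)
    class(df) <- c("who_deaths", "data.frame")
    attr(df, "unusable") <- df
    return(df)
  }
  suppressWarnings({
    df$Year <- as.integer(df$Year)
    df$Sex <- as.integer(df$Sex)
    df$Frmat <- as.integer(df$Frmat)
    df$IM_Frmat <- as.integer(df$IM_Frmat)
    df[count_cols] <- lapply(df[count_cols], as.numeric)
  })
  if (anyNA(df$Year)) stop("malformed Year in '", file, "' at data row ",
                           which(is.na(df$Year))[1L])
  if (anyNA(df$Sex) || !all(df$Sex %in% c(1L, 2L, 9L)))
    stop("malformed Sex in '", file, "' at data row ",
         which(is.na(df$Sex) | !(df$Sex %in% c(1L, 2L, 9L)))[1L],
         " (expected 1 = male, 2 = female, 9 = unspecified)")
  check_counts(df, count_cols, file, "death count")
  df[count_cols] <- lapply(df[count_cols], as.integer)
  bad_cause <- !grepl("^[A-Z][0-9]{2}[0-9]?$", df$Cause)
  if (any(bad_cause))
    stop("malformed ICD-10 cause in '", file, "' at data row ",
         which(bad_cause)[1L], ": '", df$Cause[which(bad_cause)[1L]], "'")

  if (!is.null(countries)) df <- df[df$Country %in% as.character(countries), , drop = FALSE]
  if (!is.null(years)) df <- df[df$Year %in% as.integer(years), , drop = FALSE]

  usable <- df$Frmat == 1L & df$IM_Frmat == 1L
  unusable <- df[!usable, , drop = FALSE]
  if (nrow(unusable) > 0L)
    warning(nrow(unusable), " row(s) lack the detailed infant age breakdown ",
            "and are unusable for trajectory construction (kept in attr 'unusable')")
  df <- df[usable, , drop = FALSE]

  if (nrow(df) > 0L) {
    im_sum <- df$IM_Deaths1 + df$IM_Deaths2 + df$IM_Deaths3 + df$IM_Deaths4
    bad <- which(im_sum != df$Deaths2)
    if (length(bad) > 0L)
      stop("infant consistency error in '", file, "': the four infant columns ",
           "must sum to the age-0 column (first offending data row ", bad[1L], ")")
  }

  df$Cause <- substr(df$Cause, 1L, 3L)
  if (length(causes$codes) > 0L)
    df <- df[df$Cause %in% causes$codes, , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("who_deaths", "data.frame")
  attr(df, "unusable") <- unusable
  df
}

#' Write WHO-dialect death records
#'
#' Serialises a collection of death records to the comma-delimited WHO
#' dialect so that [read_who_deaths()] on the result reproduces the
#' records exactly (round-trip identity).  An empty collection produces a
#' header-only file.
#'
#' @param records a `"who_deaths"` data frame (or any data frame with the
#'   dialect's columns).
#' @param file path to write.
#' @return `file`, invisibly.
#' @export
write_who_deaths <- function(records, file) {
  expected <- who_death_columns()
  if (!all(expected %in% names(records)))
    stop("'records' is missing dialect columns: ",
         paste(setdiff(expected, names(records)), collapse = ", "))
  utils::write.csv(as.data.frame(records)[expected], file,
                   row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Read population and live-birth records
#'
#' Reads a comma-delimited population table with columns `Country`, `Year`,
#' `Age` (single year of age, 0--94), `Pop` (living persons at that age)
#' and `LiveBirths` (births in the country-year; must be constant within a
#' country-year).  Every country-year present must report all single-year
#' ages 0--94.
#'
#' @param file path to the delimited text file.
#' @param countries,years optional filters, as in [read_who_deaths()].
#' @return A data frame of class `"who_population"`.
#' @export
read_population <- function(file, countries = NULL, years = NULL) {
  df <- utils::read.csv(file, header = TRUE, colClasses = "character",
                        check.names = FALSE, strip.white = TRUE)
  expected <- who_population_columns()
  if (!identical(names(df), expected))
    stop("'", file, "' does not match the population dialect; expected columns: ",
         paste(expected, collapse = ", "))
  suppressWarnings({
    df$Year <- as.integer(df$Year)
    df$Age <- as.integer(df$Age)
    df$Pop <- as.numeric(df$Pop)
    df$LiveBirths <- as.numeric(df$LiveBirths)
  })
  if (anyNA(df$Year) || anyNA(df$Age))
    stop("malformed Year/Age in '", file, "'")
  check_counts(df, c("Pop", "LiveBirths"), file, "population count")
  if (!is.null(countries)) df <- df[df$Country %in% as.character(countries), , drop = FALSE]
  if (!is.null(years)) df <- df[df$Year %in% as.integer(years), , drop = FALSE]

  key <- paste(df$Country, df$Year, df$Age)
  if (anyDuplicated(key))
    stop("duplicate (country, year, age) entry in '", file, "': ",
         key[which(duplicated(key))[1L]])
  cy <- unique(df[c("Country", "Year")])
  for (i in seq_len(nrow(cy))) {
    sub <- df[df$Country == cy$Country[i] & df$Year == cy$Year[i], ]
    missing_ages <- setdiff(0:94, sub$Age)
    if (length(missing_ages) > 0L)
      stop("population for ", cy$Country[i], " ", cy$Year[i],
           " is missing single-year ages: ",
           paste(condense_runs(missing_ages), collapse = ", "))
    if (length(unique(sub$LiveBirths)) != 1L)
      stop("inconsistent LiveBirths for ", cy$Country[i], " ", cy$Year[i])
  }
  rownames(df) <- NULL
  class(df) <- c("who_population", "data.frame")
  df
}

# internal: "81-94" style run condensation for error messages
condense_runs <- function(x) {
  x <- sort(unique(x))
  runs <- split(x, cumsum(c(1L, diff(x) != 1L)))
  vapply(runs, function(r)
    if (length(r) == 1L) as.character(r) else paste0(r[1L], "-", r[length(r)]),
    character(1L))
}

#' Default country and calendar-year configuration
#'
#' The nine European countries and ICD-10 calendar spans used for the
#' default "large population": Denmark 1994--2009, Finland 1996--2015,
#' Norway 1996--2015, Sweden 1997--2015, Austria 2002--2016, the Czech
#' Republic 1994--2015, Hungary 1996--2015, Poland 1999--2015 and
#' Slovakia 1996--2014 -- the spans in which the detailed infant age
#' breakdown and the ICD-10 are jointly available.
#'
#' @return Data frame with columns `country`, `first_year`, `last_year`.
#' @export
eu9_country_years <- function() {
  data.frame(
    country = c("Denmark", "Finland", "Norway", "Sweden", "Austria",
                "Czech Republic", "Hungary", "Poland", "Slovakia"),
    first_year = c(1994L, 1996L, 1996L, 1997L, 2002L, 1994L, 1996L, 1999L, 1996L),
    last_year  = c(2009L, 2015L, 2015L, 2015L, 2016L, 2015L, 2015L, 2015L, 2014L),
    stringsAsFactors = FALSE
  )
}
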