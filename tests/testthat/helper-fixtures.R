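# Fixture builders: everything is generated in code at test time.

# A full WHO-dialect death row from per-schema-bin counts (26 bins),
# plus optional 95+ and unknown-age counts.
make_death_row <- function(country, year, cause, bin_counts,
                           deaths_95plus = 0L, deaths_unknown = 0L,
                           sex = 9L, frmat = 1L, im_frmat = 1L) {
  stopifnot(length(bin_counts) == 26L)
  row <- data.frame(Country = country, Admin1 = "", SubDiv = "",
                    Year = as.integer(year), List = "103", Cause = cause,
                    Sex = as.integer(sex), Frmat = as.integer(frmat),
                    IM_Frmat = as.integer(im_frmat),
                    stringsAsFactors = FALSE)
  d <- integer(26)
  d[2] <- sum(bin_counts[1:4])              # age 0
  d[3:6] <- bin_counts[5:8]                 # ages 1-4
  d[7:24] <- bin_counts[9:26]               # 5-year groups to [90,95)
  d[25] <- deaths_95plus
  d[26] <- deaths_unknown
  d[1] <- sum(d[2:26])
  dd <- as.data.frame(as.list(d))
  names(dd) <- paste0("Deaths", 1:26)
  im <- as.data.frame(as.list(bin_counts[1:4]))
  names(im) <- paste0("IM_Deaths", 1:4)
  cbind(row, dd, im)
}

write_deaths_file <- function(rows, file = tempfile(fileext = ".csv")) {
  df <- do.call(rbind, rows)
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
  file
}

# Population fixture: constant population at every single-year age.
make_population_df <- function(country, year, pop = 1e6, births = pop,
                               ages = 0:94) {
  data.frame(Country = country, Year = as.integer(year), Age = ages,
             Pop = rep_len(pop, length(ages)), LiveBirths = births,
             stringsAsFactors = FALSE)
}

write_population_file <- function(dfs, file = tempfile(fileext = ".csv")) {
  df <- do.call(rbind, dfs)
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
  file
}

# Random but valid death records for round-trip properties.
random_death_rows <- function(n, seed) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    make_death_row(
      country = sample(c("Aland", "Borduria", "Syldavia"), 1L),
      year = sample(1995:2015, 1L),
      cause = sprintf("%s%02d", sample(LETTERS, 1L), sample(0:99, 1L)),
      bin_counts = as.integer(rpois(26, lambda = 8)),
      deaths_95plus = as.integer(rpois(1, 2)),
      deaths_unknown = as.integer(rpois(1, 1)),
      sex = sample(c(1L, 2L, 9L), 1L)
    )
  })
}

# Rate table with prescribed rates per 1e7 person-years at the WHO bins
# (L = 1e7 so that mu == D / width numerically; D = mu * width).
toy_rate_table <- function(mu, schema = halleymort::who_age_schema()) {
  stopifnot(length(mu) == nrow(schema))
  bins <- data.frame(A = schema$A, B = schema$B, width = schema$width,
                     D = mu * schema$width, L = 1e7,
                     PY = 1e7 * schema$width)
  halleymort::mortality_rates(bins)
}

# Rate table following an exact functional hazard mu(x) (per 1e7).
functional_rate_table <- function(f, schema = halleymort::who_age_schema()) {
  x <- (schema$A + schema$B) / 2
  toy_rate_table(f(x), schema)
}
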