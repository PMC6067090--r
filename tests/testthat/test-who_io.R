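test_that("cause ranges expand to inclusive, deduplicated 3-character sets", {
  cs <- parse_cause_range("Q00-Q07")
  expect_s3_class(cs, "cause_set")
  expect_identical(cs$codes, sprintf("Q%02d", 0:7))
  expect_length(parse_cause_range("G00-G99")$codes, 100L)
  expect_identical(parse_cause_range("Q05")$codes, "Q05")
  expect_identical(parse_cause_range("Q03,Q01-Q02,Q03")$codes,
                   c("Q01", "Q02", "Q03"))
  # any letter: a full X00-X99 block has exactly 100 codes
  for (letter in c("A", "J", "X")) {
    expect_length(parse_cause_range(sprintf("%s00-%s99", letter, letter))$codes,
                  100L)
  }
  expect_length(parse_cause_range("ALL")$codes, 0L)
})

test_that("malformed cause specifications are rejected with a message", {
  expect_error(parse_cause_range("Q07-Q00"), "reversed")
  expect_error(parse_cause_range("Q00-G07"), "prefix")
  expect_error(parse_cause_range("Q0"), "malformed")
  expect_error(parse_cause_range("q00-q07"), "malformed")
  expect_error(parse_cause_range("Q00 - Q07, "), "empty|malformed")
})

test_that("write then read is the identity on valid record collections", {
  for (seed in c(1L, 42L)) {
    rows <- random_death_rows(6L, seed)
    file <- write_deaths_file(rows)
    back <- read_who_deaths(file)
    orig <- do.call(rbind, rows)
    expect_equal(nrow(back), nrow(orig))
    for (col in names(orig)) {
      expect_equal(as.vector(back[[col]]), as.vector(orig[[col]]),
                   info = paste("column", col, "seed", seed),
                   ignore_attr = TRUE, tolerance = 0)
    }
    # second pass: write what was read, read again -> identical
    file2 <- tempfile(fileext = ".csv")
    write_who_deaths(back, file2)
    back2 <- read_who_deaths(file2)
    expect_identical(as.data.frame(back2), as.data.frame(back))
  }
})

test_that("an empty collection round-trips through a header-only file", {
  rows <- random_death_rows(1L, 5L)
  file <- write_deaths_file(rows)
  empty <- read_who_deaths(file, countries = "Nowhere")
  expect_equal(nrow(empty), 0L)
  f2 <- tempfile(fileext = ".csv")
  write_who_deaths(empty, f2)
  expect_equal(length(readLines(f2)), 1L)   # header only
  expect_equal(nrow(read_who_deaths(f2)), 0L)
})

test_that("unspecified sex is encoded and recovered", {
  row <- make_death_row("Aland", 2000, "Q03", rep(1L, 26), sex = 9L)
  file <- write_deaths_file(list(row))
  expect_equal(read_who_deaths(file)$Sex, 9L)
})

test_that("four-character causes are tallied under their three-character prefix", {
  row <- make_death_row("Aland", 2000, "Q038", c(4L, rep(0L, 25)))
  file <- write_deaths_file(list(row))
  got <- read_who_deaths(file, causes = "Q00-Q07")
  expect_equal(nrow(got), 1L)
  expect_equal(got$Cause, "Q03")
  # outside the set -> dropped
  expect_equal(nrow(read_who_deaths(file, causes = "Q04-Q07")), 0L)
})

test_that("country/year filtering drops rows and is idempotent", {
  rows <- list(make_death_row("Aland", 2000, "Q03", rep(1L, 26)),
               make_death_row("Borduria", 2001, "Q04", rep(2L, 26)))
  file <- write_deaths_file(rows)
  got <- read_who_deaths(file, countries = "Aland")
  expect_equal(unique(got$Country), "Aland")
  got2 <- read_who_deaths(file, causes = "Q00-Q07")
  refiltered <- got2[got2$Cause %in% parse_cause_range("Q00-Q07")$codes, ]
  expect_equal(nrow(refiltered), nrow(got2))
  expect_equal(nrow(read_who_deaths(file, years = 2001)), 1L)
})

test_that("rows without the detailed infant breakdown are reported unusable", {
  rows <- list(make_death_row("Aland", 2000, "Q03", rep(1L, 26)),
               make_death_row("Aland", 2000, "Q04", rep(1L, 26), frmat = 2L),
               make_death_row("Aland", 2000, "Q05", rep(1L, 26), im_frmat = 8L))
  file <- write_deaths_file(rows)
  expect_warning(got <- read_who_deaths(file), "unusable")
  expect_equal(nrow(got), 1L)
  expect_equal(nrow(attr(got, "unusable")), 2L)
})

test_that("infant columns that do not sum to the age-0 column are an error", {
  row <- make_death_row("Aland", 2000, "Q03", rep(1L, 26))
  row$Deaths2 <- row$Deaths2 + 1L
  file <- write_deaths_file(list(row))
  expect_error(read_who_deaths(file), "infant consistency")
})

test_that("malformed rows are rejected with their row number", {
  row <- make_death_row("Aland", 2000, "Q03", rep(1L, 26))
  row$Deaths5 <- -3L
  file <- write_deaths_file(list(row))
  expect_error(read_who_deaths(file), "row 1")
  row2 <- make_death_row("Aland", 2000, "BAD!", rep(1L, 26))
  file2 <- write_deaths_file(list(row2))
  expect_error(read_who_deaths(file2), "cause")
})

test_that("population files require complete single-year ages per country-year", {
  ok <- make_population_df("Aland", 2000)
  f <- write_population_file(list(ok))
  got <- read_population(f)
  expect_equal(nrow(got), 95L)
  # duplicate age
  dup <- rbind(ok, ok[1, ])
  expect_error(read_population(write_population_file(list(dup))), "duplicate")
  # gap: ages 0-80 only, error names the missing run
  gap <- ok[ok$Age <= 80, ]
  expect_error(read_population(write_population_file(list(gap))), "81-94")
})
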