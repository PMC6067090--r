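test_that("raw WHO columns map onto the detailed schema; 95+/unknown excluded", {
  bins <- c(10L, 5L, 3L, 2L, rep(0L, 22))
  row <- make_death_row("Aland", 2000, "Q03", bins,
                        deaths_95plus = 7L, deaths_unknown = 4L)
  m <- map_raw_ages(row)
  expect_equal(dim(m), c(1L, 26L))
  expect_equal(as.vector(m[1, 1:4]), c(10, 5, 3, 2))
  expect_equal(sum(m), 20)                # 95+ and unknown not mapped
  # all-zero record maps to all-zero bins
  zrow <- make_death_row("Aland", 2000, "Q03", rep(0L, 26))
  expect_equal(sum(map_raw_ages(zrow)), 0)
  # a non-WHO schema cannot host the fixed file columns
  expect_error(map_raw_ages(row, age_schema(c(0, 1, 5))), "WHO")
})

test_that("sub-year entrants follow survivor depletion from live births", {
  expect_equal(infant_entrants(1000, c(10, 5, 3, 2)), c(1000, 990, 985, 982))
  expect_equal(infant_entrants(1000, c(0, 0, 0, 0)), rep(1000, 4))
  expect_error(infant_entrants(1000, c(1001, 0, 0, 0)), "exceed")
  expect_error(infant_entrants(0, c(0, 0, 0, 0)), "positive")
})

test_that("rates are deaths per person-year at the interval midpoint", {
  bins <- data.frame(A = c(0, 1), B = c(1 / 365, 2),
                     width = c(1 / 365, 1),
                     D = c(100, 10), L = c(1e6, 1e6),
                     PY = c(1e6 / 365, 1e6))
  r <- mortality_rates(bins)
  expect_equal(r$mu, c(365000, 100))      # 100*365/1e6*1e7 ; 10/1e6*1e7
  expect_equal(r$x, c(1 / 730, 1.5))
  # zero deaths give rate zero; zero exposure is flagged, not dropped
  bins$D <- c(0, 5); bins$PY[2] <- 0; bins$L[2] <- 0
  r2 <- mortality_rates(bins)
  expect_equal(nrow(r2), 2L)
  expect_equal(r2$mu[1], 0)
  expect_false(r2$usable[2])
  expect_true(is.na(r2$mu[2]))
})

test_that("representative age is the arithmetic mean of the endpoints", {
  expect_equal(representative_age(5, 10), 7.5)
  expect_equal(representative_age(0, 1 / 365), 1 / 730)
  expect_equal(representative_age(90, 95), 92.5)
  expect_error(representative_age(5, 5), "A < B")
})

test_that("pooling sums deaths and entrants bin-wise over country-years", {
  # hand-set two-country fixture
  binsA <- c(10L, 5L, 3L, 2L, 1L, 0L, 2L, 1L, 4L, rep(0L, 17))
  binsB <- c(20L, 0L, 1L, 4L, 2L, 3L, 0L, 0L, 6L, rep(1L, 17))
  rows <- list(make_death_row("Aland", 2000, "Q03", binsA),
               make_death_row("Borduria", 2000, "Q03", binsB))
  file <- write_deaths_file(rows)
  deaths <- read_who_deaths(file)
  pops <- list(make_population_df("Aland", 2000, pop = 5e5, births = 1000),
               make_population_df("Borduria", 2000, pop = 3e5, births = 2000))
  population <- read_population(write_population_file(pops))
  pooled <- halley_pool(deaths, population)

  # deaths: bin-wise hand sums
  expect_equal(pooled$D, binsA + binsB)
  expect_equal(sum(pooled$D), sum(binsA) + sum(binsB))   # conservation
  # entrants: census counts at entry age for bins >= 1 year
  expect_equal(pooled$L[5:26], rep(5e5 + 3e5, 22))
  # sub-year bins: births minus prior infant deaths, summed over countries
  expect_equal(pooled$L[1:4],
               c(1000, 990, 985, 982) + c(2000, 1980, 1980, 1979))
  expect_equal(pooled$PY, pooled$L * pooled$width)
})

test_that("duplicating every country-year leaves all rates unchanged", {
  bins <- c(3L, 1L, 0L, 2L, 1L, 1L, 0L, 0L, 5L, rep(2L, 17))
  r1 <- make_death_row("Aland", 2000, "Q03", bins)
  r2 <- make_death_row("Aland", 2001, "Q03", bins)    # identical second year
  p1 <- make_population_df("Aland", 2000, pop = 1e5, births = 5e4)
  p2 <- make_population_df("Aland", 2001, pop = 1e5, births = 5e4)

  one <- mortality_rates(halley_pool(
    read_who_deaths(write_deaths_file(list(r1))),
    read_population(write_population_file(list(p1)))))
  two <- mortality_rates(halley_pool(
    read_who_deaths(write_deaths_file(list(r1, r2))),
    read_population(write_population_file(list(p1, p2)))))
  expect_equal(two$D, 2 * one$D)
  expect_equal(two$L, 2 * one$L)
  expect_equal(two$mu, one$mu)
})

test_that("a country-year with deaths but no population is an error", {
  row <- make_death_row("Aland", 2000, "Q03", rep(1L, 26))
  deaths <- read_who_deaths(write_deaths_file(list(row)))
  population <- read_population(write_population_file(
    list(make_population_df("Borduria", 2000))))
  expect_error(halley_pool(deaths, population), "population missing")
})

test_that("cause proportions sum to 100 within bins and overall", {
  # first-day bin: 544 of 1100 deaths in one subcategory
  r1 <- make_death_row("Aland", 2000, "Q00", c(544L, rep(0L, 25)))
  r2 <- make_death_row("Aland", 2000, "Q03", c(556L, rep(0L, 25)))
  # a later bin split 25/75; one bin with a single cause
  r3 <- make_death_row("Aland", 2000, "Q00", c(0L, 0L, 0L, 0L, 25L, 40L, rep(0L, 20)))
  r4 <- make_death_row("Aland", 2000, "Q03", c(0L, 0L, 0L, 0L, 75L, rep(0L, 21)))
  deaths <- read_who_deaths(write_deaths_file(list(r1, r2, r3, r4)))
  cp <- cause_proportions(deaths)

  first_day <- cp$by_bin[cp$by_bin$label == "[0,0.00273973)", ]
  expect_equal(first_day$pct[first_day$cause == "Q00"], 544 / 1100 * 100)
  bin5 <- cp$by_bin[cp$by_bin$label == "[1,2)", ]
  expect_equal(sort(bin5$pct), c(25, 75))
  bin6 <- cp$by_bin[cp$by_bin$label == "[2,3)", ]
  expect_equal(bin6$pct[bin6$cause == "Q00"], 100)

  # empty bins report missing proportions
  empty <- cp$by_bin[cp$by_bin$label == "[90,95)", ]
  expect_true(all(is.na(empty$pct)))
  # per-bin and overall sums
  sums <- tapply(cp$by_bin$pct, cp$by_bin$label, sum)
  expect_true(all(abs(sums[!is.na(sums)] - 100) < 1e-9))
  expect_equal(sum(cp$overall$pct), 100)
})
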