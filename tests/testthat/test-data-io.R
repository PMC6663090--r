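write_weather_csv <- function(df, path = tempfile(fileext = ".csv")) {
  names(df) <- c("DATE", "TAVG", "ADPT", "AWND", "PRCP", "SNOW")[seq_along(df)]
  write.csv(df, path, row.names = FALSE)
  path
}

test_that("weather files are parsed, sorted, and validated", {
  df <- data.frame(d = c("2015-01-02", "2015-01-01", "2015-01-03"),
                   t = c(1, 2, 3), dp = c(0, 1, 2), w = c(5, 6, 7),
                   p = c(0, 1.2, 0), s = c(0, 0, 1))
  w <- read_weather(write_weather_csv(df))
  expect_equal(nrow(w), 3)
  # shuffled input comes back in independent sort order
  expect_equal(w$date, sort(as.Date(df$d)))
  expect_equal(w$temp_c, df$t[order(as.Date(df$d))])
  expect_false(any(w$missing))

  # blank cell: flagged missing with a warning, not dropped
  df$t[2] <- ""
  expect_warning(w2 <- read_weather(write_weather_csv(df)), "missing")
  expect_equal(sum(w2$missing), 1)
  expect_true(w2$missing[w2$date == as.Date("2015-01-01")])

  # non-numeric field and bad date are load errors naming the row
  df$t[2] <- "abc"
  expect_error(read_weather(write_weather_csv(df)), "non-numeric.*row 2")
  df$t[2] <- "1"
  df$d[1] <- "not-a-date"
  expect_error(read_weather(write_weather_csv(df)), "date")
})

test_that("daily aggregation counts incidents per bucket with zero fill", {
  days <- as.Date("2016-05-01") + 0:4
  crimes <- data.frame(
    occurred_at = as.POSIXct(paste(rep(days[2], 3), c("01:00", "13:00", "23:59"))),
    date = rep(days[2], 3),
    offense_group = c("Simple Assault", "Simple Assault", "Larceny"),
    zip_area = NA_character_)
  agg <- aggregate_daily_crimes(crimes, date_range = range(days))
  expect_equal(nrow(agg), 5)
  expect_equal(agg$violent[agg$date == days[2]], 2)
  expect_equal(agg$larceny[agg$date == days[2]], 1)
  expect_true(all(agg$violent[agg$date != days[2]] == 0))

  # empty incident list: all-zero rows for every day in range
  agg0 <- aggregate_daily_crimes(crimes[0, ], date_range = range(days))
  expect_equal(nrow(agg0), 5)
  expect_true(all(agg0$violent == 0 & agg0$larceny == 0))

  # unmapped labels: warning + ignored bucket, or error in strict mode
  crimes$offense_group[1] <- "Jaywalking"
  expect_warning(agg1 <- aggregate_daily_crimes(crimes, date_range = range(days)),
                 "Jaywalking")
  expect_equal(agg1$ignored[agg1$date == days[2]], 1)
  expect_error(
    suppressWarnings(aggregate_daily_crimes(crimes, date_range = range(days),
                                            strict = TRUE)),
    "Jaywalking")
})

test_that("random incident streams match a brute-force tally", {
  set.seed(42)
  days <- as.Date("2016-01-01") + 0:29
  n <- 1000
  labels <- c("Simple Assault", "Aggravated Assault", "Larceny", "Vandalism")
  crimes <- data.frame(
    occurred_at = as.POSIXct(sample(days, n, replace = TRUE)) +
      runif(n, 0, 86000),
    date = as.Date(character(n)),
    offense_group = sample(labels, n, replace = TRUE),
    zip_area = NA_character_)
  crimes$date <- as.Date(format(crimes$occurred_at, "%Y-%m-%d"))
  agg <- aggregate_daily_crimes(crimes, date_range = range(days))
  omap <- default_offense_map()
  bucket <- unname(omap[crimes$offense_group])
  expect_equal(agg$larceny, oracle_tally(crimes$date, bucket, days, "larceny"))
  expect_equal(agg$aggravated_assault,
               oracle_tally(crimes$date, bucket, days, "aggravated_assault"))
  # violent total includes aggravated assaults
  expect_equal(agg$violent,
               oracle_tally(crimes$date, bucket, days, "violent") +
                 agg$aggravated_assault)
  # conservation: every incident lands in exactly one reported column
  expect_equal(sum(agg$violent + agg$larceny + agg$ignored), n)
})

test_that("calendar covariates encode season, weekday and month structure", {
  dates <- seq(as.Date("2016-07-01"), as.Date("2016-07-31"), by = "day")
  weather <- data.frame(date = dates, heat_index_c = 25, prcp_mm = 0,
                        wind = 10, snow_flag = 0)
  weather$prcp_mm[3] <- 4.2
  cov <- build_covariates(weather)
  jul4 <- cov[cov$date == as.Date("2016-07-04"), ]
  expect_equal(jul4$Holidays, 1)
  expect_equal(jul4$Summer, 1)
  expect_equal(cov$MidDayMonth, as.integer(format(dates, "%d") == "15"))
  sat <- cov[cov$date == as.Date("2016-07-02"), ]  # a Saturday
  expect_equal(sat$Weekend, 1)
  expect_equal(sat$Friday, 0)
  expect_equal(cov$LastDayMonth[cov$date == as.Date("2016-07-31")], 1)
  # exactly one season flag per day; Rain iff positive precipitation
  expect_true(all(cov$Fall + cov$Winter + cov$Spring + cov$Summer == 1))
  expect_equal(cov$Rain, as.integer(weather$prcp_mm > 0))
  # a calendar that misses the year is an error naming the gap
  expect_error(
    build_covariates(weather, holidays = us_federal_holidays(1999)),
    "2016")
})

test_that("study table round-trips through CSV field for field", {
  synth <- generate_synthetic(synthetic_config(n_days = 90, seed = 11))
  path <- tempfile(fileext = ".csv")
  write_study_table(synth$study, path)
  back <- read_study_table(path)
  expect_equal(back$date, synth$study$date)
  expect_equal(back$violent, synth$study$violent)
  for (nm in names(synth$study)) {
    if (is.numeric(synth$study[[nm]])) {
      expect_equal(back[[nm]], synth$study[[nm]], tolerance = 1e-10)
    }
  }
  # calendar completeness: one row per day in range, always
  expect_equal(nrow(back),
               as.integer(diff(range(back$date))) + 1L)
})

test_that("materialized incidents re-aggregate to the generated counts", {
  synth <- generate_synthetic(synthetic_config(n_days = 70, seed = 5))
  inc <- synthetic_incidents(synth, seed = 2)
  agg <- aggregate_daily_crimes(inc, date_range = range(synth$study$date))
  expect_equal(agg$violent, synth$study$violent)
  expect_equal(agg$aggravated_assault, synth$study$aggravated_assault)
  expect_equal(agg$larceny, synth$study$larceny)
  expect_equal(sum(agg$violent + agg$larceny + agg$ignored), nrow(inc))
})

test_that("raw CSVs flow through to a full study table", {
  synth <- generate_synthetic(synthetic_config(n_days = 70, seed = 8))
  wpath <- tempfile(fileext = ".csv")
  names_map <- weather_column_map()
  wdf <- synth$weather[c("date", "temp_c", "dewpoint_c", "wind",
                         "prcp_mm", "snow_flag")]
  names(wdf) <- unname(names_map[names(wdf)])
  write.csv(wdf, wpath, row.names = FALSE)
  inc <- synthetic_incidents(synth, seed = 3)
  cpath <- tempfile(fileext = ".csv")
  write.csv(data.frame(OCCURRED_ON_DATE = format(inc$occurred_at),
                       OFFENSE_CODE_GROUP = inc$offense_group,
                       ZIP = inc$zip_area), cpath, row.names = FALSE)
  st <- build_study_table(read_weather(wpath), read_crimes(cpath))
  expect_equal(nrow(st), 70)
  expect_equal(st$violent, synth$study$violent)
  expect_equal(st$heat_index_c, synth$study$heat_index_c, tolerance = 1e-6)
  expect_equal(st$Rain, synth$study$Rain)
})
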