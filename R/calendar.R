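#' US federal holidays
#'
#' Computes the dates of the ten classical US federal holidays for the
#' given years (New Year's Day, Martin Luther King Jr. Day, Washington's
#' Birthday, Memorial Day, Independence Day, Labor Day, Columbus Day,
#' Veterans Day, Thanksgiving, Christmas).  Observed-day shifting of
#' weekend holidays is not applied: the flag marks the calendar day
#' itself, which is what matters for daily crime counts.
#'
#' @param years integer vector of calendar years.
#' @return A \code{Date} vector, sorted.
#' @export
us_federal_holidays <- function(years) {
  nth_weekday <- function(year, month, wday, n) {
    # wday: 0 = Sunday ... 6 = Saturday
    first <- as.Date(sprintf("%d-%02d-01", year, month))
    shift <- (wday - as.POSIXlt(first)$wday) %% 7
    first + shift + 7 * (n - 1)
  }
  last_weekday <- function(year, month, wday) {
    last <- seq(as.Date(sprintf("%d-%02d-01", year, month)),
                by = "month", length.out = 2)[2] - 1
    last - (as.POSIXlt(last)$wday - wday) %% 7
  }
  out <- lapply(years, function(y) {
    c(as.Date(sprintf("%d-01-01", y)),
      nth_weekday(y, 1, 1, 3),     # MLK: 3rd Monday of January
      nth_weekday(y, 2, 1, 3),     # Washington: 3rd Monday of February
      last_weekday(y, 5, 1),       # Memorial: last Monday of May
      as.Date(sprintf("%d-07-04", y)),
      nth_weekday(y, 9, 1, 1),     # Labor: 1st Monday of September
      nth_weekday(y, 10, 1, 2),    # Columbus: 2nd Monday of October
      as.Date(sprintf("%d-11-11", y)),
      nth_weekday(y, 11, 4, 4),    # Thanksgiving: 4th Thursday of November
      as.Date(sprintf("%d-12-25", y)))
  })
  sort(do.call(c, out))
}

#' Meteorological season of a date
#'
#' @param dates a \code{Date} vector.
#' @param rule season definition; only \code{"meteorological"}
#'   (Winter = Dec-Feb, Spring = Mar-May, Summer = Jun-Aug, Fall = Sep-Nov)
#'   is built in, but a named function \code{Date -> character} may be
#'   supplied instead.
#' @return Character vector in \code{c("Winter","Spring","Summer","Fall")}.
#' @export
season_of <- function(dates, rule = "meteorological") {
  if (is.function(rule)) return(rule(dates))
  stopifnot(identical(rule, "meteorological"))
  m <- as.integer(format(dates, "%m"))
  c("Winter", "Winter", "Spring", "Spring", "Spring", "Summer",
    "Summer", "Summer", "Fall", "Fall", "Fall", "Winter")[m]
}

# canonical covariate column order used across the package
covariate_names <- function() {
  c("Fall", "Winter", "Spring", "Summer", "Friday", "Weekend",
    "FirstDayMonth", "MidDayMonth", "LastDayMonth", "Snow",
    "Holidays", "Events", "Wind", "Rain", "HeatIndex")
}

#' Build the per-day background-covariate columns
#'
#' Derives the calendar and weather covariates used by the design and
#' analysis stages: season flags (exactly one per day), \code{Friday},
#' \code{Weekend}, first/fifteenth/last day of the month, \code{Snow},
#' \code{Holidays} and \code{Events} (from the supplied calendars),
#' continuous \code{Wind} and \code{HeatIndex}, and binary \code{Rain}
#' (precipitation strictly greater than 0 mm).
#'
#' @param weather data frame with columns \code{date}, \code{heat_index_c},
#'   \code{prcp_mm}, \code{wind}, \code{snow_flag}.
#' @param holidays \code{Date} vector of holiday dates; must cover the
#'   weather date range (see \code{\link{us_federal_holidays}}).
#' @param events \code{Date} vector of large-event dates (default none).
#' @param season_rule passed to \code{\link{season_of}}.
#' @return Data frame with column \code{date} followed by the covariates
#'   in canonical order.
#' @export
build_covariates <- function(weather, holidays = NULL,
                             events = as.Date(character()),
                             season_rule = "meteorological") {
  need <- c("date", "heat_index_c", "prcp_mm", "wind", "snow_flag")
  miss <- setdiff(need, names(weather))
  if (length(miss)) {
    stop("build_covariates: missing weather columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  dates <- as.Date(weather$date)
  years <- unique(as.integer(format(dates, "%Y")))
  if (is.null(holidays)) holidays <- us_federal_holidays(years)
  hol_years <- unique(as.integer(format(holidays, "%Y")))
  uncovered <- setdiff(years, hol_years)
  if (length(uncovered)) {
    stop("build_covariates: holiday calendar does not cover year(s) ",
         paste(uncovered, collapse = ", "), call. = FALSE)
  }
  season <- season_of(dates, season_rule)
  wday <- as.POSIXlt(dates)$wday            # 0 = Sunday
  dom <- as.integer(format(dates, "%d"))
  fom <- as.Date(format(dates, "%Y-%m-01"))
  month_last <- as.integer(format(as.Date(format(fom + 32, "%Y-%m-01")) - 1, "%d"))
  out <- data.frame(
    date = dates,
    Fall = as.integer(season == "Fall"),
    Winter = as.integer(season == "Winter"),
    Spring = as.integer(season == "Spring"),
    Summer = as.integer(season == "Summer"),
    Friday = as.integer(wday == 5),
    Weekend = as.integer(wday %in% c(0, 6)),
    FirstDayMonth = as.integer(dom == 1),
    MidDayMonth = as.integer(dom == 15),
    LastDayMonth = as.integer(dom == month_last),
    Snow = as.integer(weather$snow_flag > 0),
    Holidays = as.integer(dates %in% holidays),
    Events = as.integer(dates %in% events),
    Wind = as.numeric(weather$wind),
    Rain = as.integer(weather$prcp_mm > 0),
    HeatIndex = as.numeric(weather$heat_index_c)
  )
  out
}
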