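#' Column mapping for a daily-summary weather CSV
#'
#' Portals drift in their header names, so the mapping from file columns
#' to the canonical fields is configuration.  Defaults follow NOAA Climate
#' Data Online daily summaries.
#'
#' @param date,temp_c,dewpoint_c,wind,prcp_mm,snow_flag file column names.
#' @return Named character vector.
#' @export
weather_column_map <- function(date = "DATE", temp_c = "TAVG",
                               dewpoint_c = "ADPT", wind = "AWND",
                               prcp_mm = "PRCP", snow_flag = "SNOW") {
  c(date = date, temp_c = temp_c, dewpoint_c = dewpoint_c,
    wind = wind, prcp_mm = prcp_mm, snow_flag = snow_flag)
}

#' Column mapping for an incident-report CSV
#'
#' Defaults follow the Boston data-portal incident schema.
#'
#' @param occurred_at,offense_group,zip_area file column names;
#'   \code{zip_area} may be \code{NA} when the file has no location column.
#' @return Named character vector.
#' @export
crime_column_map <- function(occurred_at = "OCCURRED_ON_DATE",
                             offense_group = "OFFENSE_CODE_GROUP",
                             zip_area = "ZIP") {
  c(occurred_at = occurred_at, offense_group = offense_group,
    zip_area = zip_area)
}

#' Read a daily weather table
#'
#' Reads a comma-separated, headered weather file, renames columns via the
#' mapping, parses dates, and returns records sorted by date.  Rows with
#' missing numeric fields are kept but flagged (\code{missing = TRUE}) and
#' reported with a warning; downstream stages exclude them rather than
#' imputing exposures.
#'
#' @param path CSV file path.
#' @param column_map see \code{\link{weather_column_map}}.
#' @return Data frame with columns \code{date}, \code{temp_c},
#'   \code{dewpoint_c}, \code{wind}, \code{prcp_mm}, \code{snow_flag},
#'   \code{missing}, sorted by date.
#' @export
read_weather <- function(path, column_map = weather_column_map()) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(column_map, names(raw))
  if (length(miss)) {
    stop("read_weather: columns not found in ", path, ": ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  out <- data.frame(date = raw[[column_map[["date"]]]])
  for (f in c("temp_c", "dewpoint_c", "wind", "prcp_mm", "snow_flag")) {
    v <- raw[[column_map[[f]]]]
    vn <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & v != "" & is.na(vn))
    if (length(bad)) {
      stop(sprintf("read_weather: non-numeric value '%s' for %s in row %d",
                   v[bad[1]], f, bad[1]), call. = FALSE)
    }
    vn[!is.na(v) & v == ""] <- NA_real_
    out[[f]] <- vn
  }
  d <- suppressWarnings(as.Date(as.character(out$date), format = "%Y-%m-%d"))
  if (anyNA(d)) {
    stop("read_weather: unparseable date '",
         out$date[which(is.na(d))[1]], "' in row ", which(is.na(d))[1],
         call. = FALSE)
  }
  out$date <- d
  if (anyDuplicated(out$date)) {
    stop("read_weather: duplicated date ",
         out$date[anyDuplicated(out$date)], call. = FALSE)
  }
  out <- out[order(out$date), , drop = FALSE]
  rownames(out) <- NULL
  out$missing <- !stats::complete.cases(
    out[c("temp_c", "dewpoint_c", "wind", "prcp_mm", "snow_flag")])
  if (any(out$missing)) {
    warning(sum(out$missing), " weather day(s) with missing fields flagged; ",
            "they are excluded from all experiments")
  }
  gaps <- diff(out$date)
  if (any(gaps > 1)) {
    warning("weather series has ", sum(gaps > 1), " calendar gap(s); ",
            "first after ", out$date[which(gaps > 1)[1]])
  }
  out
}

#' Read a crime incident table
#'
#' @param path CSV file path.
#' @param column_map see \code{\link{crime_column_map}}.
#' @param tz Olson time zone used to take the local-date part of each
#'   timestamp (default \code{"America/New_York"}).
#' @return Data frame with columns \code{occurred_at} (POSIXct),
#'   \code{date} (local date), \code{offense_group}, \code{zip_area}.
#' @export
read_crimes <- function(path, column_map = crime_column_map(),
                        tz = "America/New_York") {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- column_map[c("occurred_at", "offense_group")]
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    stop("read_crimes: columns not found in ", path, ": ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  ts <- as.POSIXct(raw[[column_map[["occurred_at"]]]], tz = tz)
  if (anyNA(ts)) {
    stop("read_crimes: unparseable timestamp in row ", which(is.na(ts))[1],
         call. = FALSE)
  }
  grp <- as.character(raw[[column_map[["offense_group"]]]])
  if (any(is.na(grp) | grp == "")) {
    stop("read_crimes: empty offense group in row ",
         which(is.na(grp) | grp == "")[1], call. = FALSE)
  }
  zip_col <- column_map[["zip_area"]]
  zip <- if (!is.na(zip_col) && zip_col %in% names(raw)) {
    as.character(raw[[zip_col]])
  } else {
    NA_character_
  }
  data.frame(occurred_at = ts,
             date = as.Date(format(ts, "%Y-%m-%d", tz = tz)),
             offense_group = grp,
             zip_area = zip,
             stringsAsFactors = FALSE)
}

#' Default offense-to-outcome mapping
#'
#' Maps incident category labels to the outcome buckets.  The default
#' violent-crime set comprises aggravated assaults, simple assaults,
#' crimes involving weapons, homicides, kidnappings, manslaughters,
#' murders, escapes, runaways, truancies, and vandalism; aggravated
#' assault is additionally counted in its own bucket, and larceny forms
#' the property-crime bucket.
#'
#' @param extra named character vector of additional label -> bucket
#'   entries (bucket in \code{c("violent","aggravated_assault","larceny",
#'   "ignored")}); later entries override defaults.
#' @return Named character vector: label -> bucket.
#' @export
default_offense_map <- function(extra = character()) {
  base <- c(
    "Aggravated Assault" = "aggravated_assault",
    "Simple Assault" = "violent",
    "Weapons Violations" = "violent",
    "Homicide" = "violent",
    "Kidnapping" = "violent",
    "Manslaughter" = "violent",
    "Murder" = "violent",
    "Escape" = "violent",
    "Runaway" = "violent",
    "Truancy" = "violent",
    "Vandalism" = "violent",
    "Larceny" = "larceny",
    "Larceny From Motor Vehicle" = "larceny"
  )
  if (length(extra)) base[names(extra)] <- extra
  bad <- setdiff(unique(base),
                 c("violent", "aggravated_assault", "larceny", "ignored"))
  if (length(bad)) {
    stop("offense map: unknown bucket(s) ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  base
}

outcome_names <- function() c("violent", "aggravated_assault", "larceny")

#' Aggregate incidents to daily outcome counts
#'
#' Tallies incidents into per-day counts for each outcome bucket.
#' Aggravated assaults count both in their own bucket and in the violent
#' total.  Every calendar day in the range appears, with zero counts on
#' incident-free days.
#'
#' @param crimes data frame as returned by \code{\link{read_crimes}}.
#' @param offense_map named vector label -> bucket
#'   (\code{\link{default_offense_map}}).
#' @param date_range \code{Date} vector of length 2 (inclusive bounds).
#' @param strict if \code{TRUE}, an unmapped label is an error; otherwise
#'   unmapped incidents are counted as ignored with a warning.
#' @return Data frame: \code{date}, \code{violent},
#'   \code{aggravated_assault}, \code{larceny}, \code{ignored}.
#' @export
aggregate_daily_crimes <- function(crimes, offense_map = default_offense_map(),
                                   date_range, strict = FALSE) {
  stopifnot(length(date_range) == 2L, date_range[1] <= date_range[2])
  days <- seq(as.Date(date_range[1]), as.Date(date_range[2]), by = "day")
  out <- data.frame(date = days, violent = 0L, aggravated_assault = 0L,
                    larceny = 0L, ignored = 0L)
  if (nrow(crimes)) {
    bucket <- unname(offense_map[crimes$offense_group])
    unmapped <- is.na(bucket)
    if (any(unmapped)) {
      labs <- unique(crimes$offense_group[unmapped])
      if (strict) {
        stop("aggregate_daily_crimes: unmapped offense label(s): ",
             paste(labs, collapse = ", "), call. = FALSE)
      }
      warning("unmapped offense label(s) counted as ignored: ",
              paste(labs, collapse = ", "))
      bucket[unmapped] <- "ignored"
    }
    keep <- crimes$date >= days[1] & crimes$date <= days[length(days)]
    idx <- match(crimes$date[keep], days)
    b <- bucket[keep]
    for (nm in c("violent", "aggravated_assault", "larceny", "ignored")) {
      tab <- tabulate(idx[b == nm], nbins = length(days))
      out[[nm]] <- out[[nm]] + tab
    }
    # aggravated assaults are part of the violent-crime total
    out$violent <- out$violent + out$aggravated_assault
  }
  out
}

#' Assemble the canonical per-day study table
#'
#' Joins weather, calendar covariates and daily crime counts into one row
#' per calendar day: the table every downstream stage consumes.  Weather
#' days flagged missing are dropped (and reported), since exposures are
#' never imputed.
#'
#' @param weather data frame from \code{\link{read_weather}}.
#' @param crimes data frame from \code{\link{read_crimes}}.
#' @inheritParams build_covariates
#' @inheritParams aggregate_daily_crimes
#' @return The study table: date, raw weather, covariates in canonical
#'   order, then outcome counts.
#' @export
build_study_table <- function(weather, crimes,
                              offense_map = default_offense_map(),
                              holidays = NULL,
                              events = as.Date(character()),
                              season_rule = "meteorological",
                              strict = FALSE) {
  if (any(weather$missing %||% FALSE)) {
    message(sum(weather$missing), " missing-weather day(s) dropped")
    weather <- weather[!weather$missing, , drop = FALSE]
  }
  weather$heat_index_c <- heat_index(weather$temp_c, weather$dewpoint_c)
  cov <- build_covariates(weather, holidays = holidays, events = events,
                          season_rule = season_rule)
  counts <- aggregate_daily_crimes(crimes, offense_map,
                                   range(weather$date), strict = strict)
  out <- cbind(
    weather[c("date", "temp_c", "dewpoint_c", "heat_index_c", "prcp_mm")],
    cov[match(weather$date, cov$date), covariate_names(), drop = FALSE],
    counts[match(weather$date, counts$date), outcome_names(), drop = FALSE]
  )
  rownames(out) <- NULL
  out
}

#' Write / read the study table
#'
#' Plain CSV round-trip of the canonical study table; re-reading
#' reproduces it field for field.
#'
#' @param study study table from \code{\link{build_study_table}}.
#' @param path CSV path.
#' @return \code{read_study_table} returns the study table.
#' @export
write_study_table <- function(study, path) {
  utils::write.csv(study, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_study_table
#' @export
read_study_table <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  out$date <- as.Date(out$date)
  int_cols <- intersect(c(covariate_names()[!covariate_names() %in%
                                              c("Wind", "HeatIndex")],
                          outcome_names()), names(out))
  for (nm in int_cols) out[[nm]] <- as.integer(out[[nm]])
  out
}
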