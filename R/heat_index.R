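#' Relative humidity from air and dew-point temperature
#'
#' Computes relative humidity as the ratio of the saturation vapor pressures
#' at the dew point and at the air temperature, using the Magnus
#' approximation (a = 17.625, b = 243.04 degC).  A dew point above the air
#' temperature is physically impossible and is clamped to 100% with a
#' warning.
#'
#' @param temp_c air temperature in degrees Celsius.
#' @param dewpoint_c dew-point temperature in degrees Celsius.
#' @return Relative humidity in percent, in (0, 100].
#' @export
#' @examples
#' relative_humidity(25, 15)
relative_humidity <- function(temp_c, dewpoint_c) {
  if (any(!is.finite(temp_c)) || any(!is.finite(dewpoint_c))) {
    stop("relative_humidity: non-finite input", call. = FALSE)
  }
  a <- 17.625
  b <- 243.04
  rh <- 100 * exp(a * dewpoint_c / (b + dewpoint_c) - a * temp_c / (b + temp_c))
  over <- rh > 100
  if (any(over)) {
    warning("dew point exceeds air temperature; relative humidity clamped to 100%")
    rh[over] <- 100
  }
  rh
}

# Rothfusz regression and adjustments, in degrees Fahrenheit
hi_fahrenheit <- function(temp_f, rh) {
  # simple formula (already the average with the air temperature);
  # the full regression only applies when apparent temperature >= 80 F
  hi <- 0.5 * (temp_f + 61 + (temp_f - 68) * 1.2 + rh * 0.094)
  hot <- hi >= 80
  if (any(hot)) {
    t <- temp_f[hot]
    h <- rh[hot]
    reg <- -42.379 + 2.04901523 * t + 10.14333127 * h - 0.22475541 * t * h -
      6.83783e-3 * t^2 - 5.481717e-2 * h^2 + 1.22874e-3 * t^2 * h +
      8.5282e-4 * t * h^2 - 1.99e-6 * t^2 * h^2
    dry <- h < 13 & t >= 80 & t <= 112
    reg[dry] <- reg[dry] -
      ((13 - h[dry]) / 4) * sqrt((17 - abs(t[dry] - 95)) / 17)
    humid <- h > 85 & t >= 80 & t <= 87
    reg[humid] <- reg[humid] +
      ((h[humid] - 85) / 10) * ((87 - t[humid]) / 5)
    hi[hot] <- reg
  }
  hi
}

#' NWS heat index from air temperature and dew point
#'
#' Apparent temperature following the U.S. National Weather Service
#' procedure: humidity is derived from the dew point, the simple
#' low-temperature formula is evaluated first, and the Rothfusz regression
#' (with the dry-air and high-humidity adjustment terms) replaces it
#' whenever the simple value reaches 80 degF.  Computation is carried out
#' in degrees Fahrenheit internally and converted back to Celsius.
#'
#' @inheritParams relative_humidity
#' @return Heat index in degrees Celsius.
#' @export
#' @examples
#' heat_index(32.2, 26)  # a hot, humid day
#' heat_index(0, -5)     # cold regime: close to the air temperature
heat_index <- function(temp_c, dewpoint_c) {
  if (any(!is.finite(temp_c)) || any(!is.finite(dewpoint_c))) {
    stop("heat_index: non-finite input", call. = FALSE)
  }
  rh <- relative_humidity(temp_c, dewpoint_c)
  temp_f <- temp_c * 9 / 5 + 32
  hi_f <- hi_fahrenheit(temp_f, rh)
  (hi_f - 32) * 5 / 9
}
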