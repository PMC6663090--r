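#' Configuration for the synthetic weather-crime generator
#'
#' Defaults emulate the structure the analysis assumes for a Boston-like
#' city: a sinusoidal seasonal heat-index cycle with day-to-day noise,
#' season-dependent rain occurrence, gamma-distributed wind, calendar
#' covariates, and NB2 daily crime counts whose log-mean carries a known
#' additive exposure effect tau.  Both potential outcomes are drawn and
#' stored for every day, so the exact finite-population AEE of any day
#' subset is available as ground truth.
#'
#' @param n_days number of days (>= 60).
#' @param start first date.
#' @param temp_mean,temp_amplitude,temp_peak_doy,temp_noise_sd annual
#'   air-temperature cycle in degC: mean level, amplitude, day-of-year of
#'   the peak, and SD of the additive daily noise.
#' @param dewpoint_offset_mean mean of the exponential temperature minus
#'   dew-point offset (degC).
#' @param rain_prob named per-season rain probabilities.
#' @param rain_mm_mean mean rainfall depth on wet days (mm).
#' @param wind_shape,wind_rate gamma parameters for daily wind speed.
#' @param zip_areas area labels used when incidents are materialized.
#' @param alpha baseline log mean of the daily violent-crime count.
#' @param gamma named covariate effects on the log mean (names must be
#'   covariate columns).
#' @param tau additive exposure effect on the log mean.
#' @param phi NB2 dispersion (variance mu + mu^2/phi).
#' @param p_aggravated probability that a violent crime is an aggravated
#'   assault (aggravated-assault counts are a binomial thinning of the
#'   violent counts, so they never exceed them).
#' @param larceny_alpha,larceny_tau,larceny_phi larceny-count model.
#' @param exposure \code{"threshold"} realizes exposure by the same
#'   heat-index class-mean rule the design stage uses (exposure then
#'   depends on season: confounding ON); \code{"randomized"} assigns
#'   exposure by a fair coin (confounding OFF).
#' @param seed integer seed.
#' @return Object of class \code{wc_synth_config}.
#' @export
synthetic_config <- function(n_days = 1200L, start = as.Date("2013-01-01"),
                             temp_mean = 10.5, temp_amplitude = 13.5,
                             temp_peak_doy = 200L, temp_noise_sd = 3.5,
                             dewpoint_offset_mean = 4,
                             rain_prob = c(Winter = 0.35, Spring = 0.35,
                                           Summer = 0.3, Fall = 0.3),
                             rain_mm_mean = 6,
                             wind_shape = 4, wind_rate = 0.4,
                             zip_areas = sprintf("021%02d", 1:10),
                             alpha = log(18),
                             gamma = c(Summer = 0.25, Winter = -0.2,
                                       Weekend = 0.10, Friday = 0.05,
                                       Wind = -0.01),
                             tau = 0.2, phi = 10,
                             p_aggravated = 0.25,
                             larceny_alpha = log(12), larceny_tau = 0.1,
                             larceny_phi = 12,
                             exposure = c("threshold", "randomized"),
                             seed = 1L) {
  exposure <- match.arg(exposure)
  if (n_days < 60L) stop("synthetic_config: n_days must be >= 60",
                         call. = FALSE)
  if (phi <= 0) stop("synthetic_config: phi must be > 0", call. = FALSE)
  if (any(rain_prob < 0 | rain_prob > 1)) {
    stop("synthetic_config: rain_prob must lie in [0,1]", call. = FALSE)
  }
  if (p_aggravated < 0 || p_aggravated > 1) {
    stop("synthetic_config: p_aggravated must lie in [0,1]", call. = FALSE)
  }
  bad <- setdiff(names(gamma), covariate_names())
  if (length(bad)) {
    stop("synthetic_config: gamma names not covariates: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(as.list(environment()), class = "wc_synth_config")
}

#' Generate a synthetic study table with stored potential outcomes
#'
#' @param config \code{\link{synthetic_config}}.
#' @return Object of class \code{wc_synth}: \code{study} (the canonical
#'   study table, observed outcomes only), \code{truth} (stored
#'   potential-outcome pairs per outcome, realized exposure \code{W},
#'   the exposure thresholds used), and \code{config}.
#' @export
generate_synthetic <- function(config) {
  stopifnot(inherits(config, "wc_synth_config"))
  set.seed(config$seed)
  n <- config$n_days
  dates <- seq(as.Date(config$start), by = "day", length.out = n)
  doy <- as.integer(format(dates, "%j"))
  temp <- config$temp_mean +
    config$temp_amplitude * cos(2 * pi * (doy - config$temp_peak_doy) / 365.25) +
    stats::rnorm(n, 0, config$temp_noise_sd)
  dew <- temp - pmax(stats::rexp(n, 1 / config$dewpoint_offset_mean), 0.2)
  season <- season_of(dates)
  rain <- stats::rbinom(n, 1, unname(config$rain_prob[season]))
  prcp <- ifelse(rain == 1,
                 stats::rgamma(n, shape = 1.2,
                               scale = config$rain_mm_mean / 1.2), 0)
  snow <- as.integer(prcp > 0 & temp < 0)
  wind <- stats::rgamma(n, shape = config$wind_shape,
                        rate = config$wind_rate)
  weather <- data.frame(date = dates, temp_c = temp, dewpoint_c = dew,
                        wind = wind, prcp_mm = prcp, snow_flag = snow)
  weather$heat_index_c <- heat_index(temp, dew)
  cov <- build_covariates(weather)

  eta0 <- config$alpha
  for (nm in names(config$gamma)) {
    eta0 <- eta0 + config$gamma[[nm]] * cov[[nm]]
  }
  y0 <- stats::rnbinom(n, size = config$phi, mu = exp(eta0))
  y1 <- stats::rnbinom(n, size = config$phi, mu = exp(eta0 + config$tau))
  a0 <- stats::rbinom(n, y0, config$p_aggravated)
  a1 <- stats::rbinom(n, y1, config$p_aggravated)
  eta_l <- eta0 - config$alpha + config$larceny_alpha
  l0 <- stats::rnbinom(n, size = config$larceny_phi, mu = exp(eta_l))
  l1 <- stats::rnbinom(n, size = config$larceny_phi,
                       mu = exp(eta_l + config$larceny_tau))

  hi <- weather$heat_index_c
  thresholds <- NULL
  if (config$exposure == "threshold") {
    classes <- boston_experiments()[c("NegativeHI", "MildHI", "HighHI")]
    w <- integer(n)
    assigned <- rep(FALSE, n)
    thresholds <- vapply(classes, function(sp) {
      inside <- in_class(hi, sp)
      if (!any(inside)) return(NA_real_)
      mean(hi[inside])
    }, numeric(1))
    for (k in seq_along(classes)) {
      inside <- in_class(hi, classes[[k]])
      w[inside] <- as.integer(hi[inside] > thresholds[[k]])
      assigned <- assigned | inside
    }
    if (any(!assigned)) {
      w[!assigned] <- as.integer(hi[!assigned] > mean(hi))
    }
  } else {
    w <- stats::rbinom(n, 1, 0.5)
  }

  study <- cbind(
    weather[c("date", "temp_c", "dewpoint_c", "heat_index_c", "prcp_mm")],
    cov[covariate_names()],
    data.frame(violent = ifelse(w == 1, y1, y0),
               aggravated_assault = ifelse(w == 1, a1, a0),
               larceny = ifelse(w == 1, l1, l0))
  )
  rownames(study) <- NULL
  truth <- list(
    dates = dates, W = w, thresholds = thresholds,
    po = list(violent = list(Y0 = y0, Y1 = y1),
              aggravated_assault = list(Y0 = a0, Y1 = a1),
              larceny = list(Y0 = l0, Y1 = l1)))
  structure(list(study = study, truth = truth, config = config,
                 weather = weather),
            class = "wc_synth")
}

#' Exact finite-population AEE of a day subset
#'
#' The estimand the pipeline targets: the mean of the stored Y(1) minus
#' the mean of the stored Y(0) over the given days.
#'
#' @param synth \code{wc_synth} (or its \code{truth} element).
#' @param dates \code{Date} vector (default: all generated days).
#' @param outcome outcome name.
#' @return The exact AEE.
#' @export
truth_aee <- function(synth, dates = NULL, outcome = "violent") {
  truth <- if (inherits(synth, "wc_synth")) synth$truth else synth
  if (is.null(dates)) dates <- truth$dates
  idx <- match(as.Date(dates), truth$dates)
  if (anyNA(idx)) {
    stop("truth_aee: unknown date ", as.Date(dates)[which(is.na(idx))[1]],
         call. = FALSE)
  }
  if (!length(idx)) stop("truth_aee: empty day subset", call. = FALSE)
  po <- truth$po[[outcome]]
  mean(po$Y1[idx]) - mean(po$Y0[idx])
}

# labels used when materializing incident rows
simple_violent_labels <- function() {
  c("Simple Assault", "Vandalism", "Weapons Violations", "Homicide",
    "Kidnapping", "Runaway")
}

#' Materialize incident-level records from a synthetic study table
#'
#' Explodes the daily counts into one incident row each, with a random
#' time of day, a uniform-multinomial zip-code area, and an offense
#' label that maps back to the originating bucket, so re-aggregation
#' through \code{\link{aggregate_daily_crimes}} reproduces the daily
#' counts exactly.
#'
#' @param synth \code{wc_synth}.
#' @param seed integer seed.
#' @param tz time zone for the timestamps.
#' @return Incident data frame with columns \code{occurred_at},
#'   \code{date}, \code{offense_group}, \code{zip_area}.
#' @export
synthetic_incidents <- function(synth, seed = 1L, tz = "America/New_York") {
  stopifnot(inherits(synth, "wc_synth"))
  set.seed(seed)
  st <- synth$study
  n_simple <- st$violent - st$aggravated_assault
  counts <- list(agg = st$aggravated_assault, simple = n_simple,
                 larceny = st$larceny)
  rows <- lapply(seq_len(nrow(st)), function(i) {
    k <- counts$agg[i] + counts$simple[i] + counts$larceny[i]
    if (k == 0) return(NULL)
    labs <- c(rep("Aggravated Assault", counts$agg[i]),
              sample(simple_violent_labels(), counts$simple[i],
                     replace = TRUE),
              rep("Larceny", counts$larceny[i]))
    # stay within the shortest (DST spring-forward) local day
    secs <- sort(stats::runif(k, 0, 82799))
    data.frame(
      occurred_at = as.POSIXct(paste(st$date[i], "00:00:00"), tz = tz) + secs,
      date = st$date[i],
      offense_group = labs,
      zip_area = sample(synth$config$zip_areas, k, replace = TRUE),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(out) <- NULL
  out
}

#' Experiment spec aligned with the synthetic generator
#'
#' For validation runs on synthetic data the propensity and outcome
#' models should span the covariates the generator actually uses; this
#' returns a heat-index experiment over the given class whose models
#' include exactly those terms (the default gamma covariates plus Rain
#' in the propensity model).
#'
#' @param config \code{\link{synthetic_config}} whose gamma names to use.
#' @param class_low,class_high heat-index class bounds in degC.
#' @return \code{\link{experiment_spec}} named \code{"SynthHI"}.
#' @export
synthetic_experiment <- function(config = synthetic_config(),
                                 class_low = 0, class_high = 24) {
  terms_out <- names(config$gamma)
  experiment_spec(
    "SynthHI", "heat_index", class_low, class_high,
    ps_formula = stats::reformulate(unique(c(terms_out, "Rain"))),
    outcome_formula = stats::reformulate(terms_out))
}
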