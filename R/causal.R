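#' Impute the missing potential outcomes of a matched sample
#'
#' Replication r uses posterior parameter draw r of the relevant arm's
#' model: for a control day the exposed-arm model imputes Y(1), for an
#' exposed day the control-arm model imputes Y(0).  Observed potential
#' outcomes are carried through unchanged in every replication, and the
#' two arms' posteriors never mix, so imputations cannot contaminate
#' each other across arms.
#'
#' @param data matched-sample data frame with column \code{arm}
#'   (\code{"exposed"}/\code{"control"}), the outcome column, and the
#'   covariates the outcome models use.
#' @param fit_exposed,fit_control per-arm \code{wc_nbfit} objects.
#' @param R number of imputation replications (default 10,000); must not
#'   exceed the retained draw count of either fit.
#' @param seed integer seed.
#' @return Object of class \code{wc_imputations}: integer matrices
#'   \code{Y1} and \code{Y0} (days x R), \code{dates}, \code{arm},
#'   \code{y_obs}, \code{outcome}.
#' @export
impute_potential_outcomes <- function(data, fit_exposed, fit_control,
                                      R = 10000L, seed = 1L) {
  outcome <- fit_exposed$outcome
  stopifnot(identical(outcome, fit_control$outcome),
            "arm" %in% names(data), outcome %in% names(data))
  S <- min(nrow(fit_exposed$draws), nrow(fit_control$draws))
  if (R > S) {
    stop("impute_potential_outcomes: R = ", R,
         " exceeds retained draw count ", S, call. = FALSE)
  }
  n <- nrow(data)
  y <- data[[outcome]]
  is_exp <- data$arm == "exposed"
  Y1 <- matrix(NA_integer_, n, R)
  Y0 <- matrix(NA_integer_, n, R)
  # observed entries: identical across replications
  Y1[is_exp, ] <- y[is_exp]
  Y0[!is_exp, ] <- y[!is_exp]
  set.seed(seed)
  draw_idx <- seq_len(R)
  if (any(!is_exp)) {
    mu1 <- nb_mu_draws(fit_exposed, data[!is_exp, , drop = FALSE], draw_idx)
    phi1 <- fit_exposed$draws[draw_idx, "phi"]
    Y1[!is_exp, ] <- stats::rnbinom(length(mu1),
                                    size = rep(phi1, each = sum(!is_exp)),
                                    mu = mu1)
  }
  if (any(is_exp)) {
    mu0 <- nb_mu_draws(fit_control, data[is_exp, , drop = FALSE], draw_idx)
    phi0 <- fit_control$draws[draw_idx, "phi"]
    Y0[is_exp, ] <- stats::rnbinom(length(mu0),
                                   size = rep(phi0, each = sum(is_exp)),
                                   mu = mu0)
  }
  structure(list(Y1 = Y1, Y0 = Y0, dates = data$date,
                 arm = data$arm, y_obs = y, outcome = outcome,
                 R = R, seed = seed),
            class = "wc_imputations")
}

#' Posterior of the finite-population average exposure effect
#'
#' For each imputation replication the AEE is the mean over matched days
#' of the unit-level effects Y_i(1) - Y_i(0) (equivalently, the mean of
#' the Y(1) column minus the mean of the Y(0) column).  The summary is
#' the posterior mean and the equal-tailed 95% interval of the R
#' replication-level values.
#'
#' @param imp \code{wc_imputations}.
#' @param level interval level (default 0.95).
#' @param point \code{"mean"} (default) or \code{"median"}.
#' @return Object of class \code{wc_aee}: \code{draws}, \code{estimate},
#'   \code{interval}, \code{N}, \code{level}, \code{outcome}.
#' @export
compute_aee <- function(imp, level = 0.95, point = c("mean", "median")) {
  point <- match.arg(point)
  if (anyNA(imp$Y1) || anyNA(imp$Y0)) {
    bad <- which(is.na(imp$Y1) | is.na(imp$Y0), arr.ind = TRUE)[1, ]
    stop("compute_aee: missing potential outcome for day ",
         imp$dates[bad[1]], ", replication ", bad[2], call. = FALSE)
  }
  draws <- colMeans(imp$Y1) - colMeans(imp$Y0)
  est <- if (point == "mean") mean(draws) else stats::median(draws)
  structure(list(draws = draws, estimate = est,
                 interval = eti(draws, level), N = nrow(imp$Y1),
                 level = level, outcome = imp$outcome),
            class = "wc_aee")
}

#' @export
print.wc_aee <- function(x, ...) {
  cat(sprintf("AEE (%s): %.2f [%.2f; %.2f] over N = %d matched days\n",
              x$outcome, x$estimate, x$interval[1], x$interval[2], x$N))
  invisible(x)
}

#' Absolute change in crime count over a number of days
#'
#' Scales the AEE point estimate (and interval) by a day count, e.g. the
#' additional crimes expected had thirty cold days been temperate.
#'
#' @param aee \code{wc_aee}, or a single numeric point estimate.
#' @param n_days number of days (> 0).
#' @return List: \code{change}, \code{interval} (NA when a bare number
#'   was supplied), \code{n_days}.
#' @export
absolute_change <- function(aee, n_days) {
  stopifnot(n_days > 0)
  if (inherits(aee, "wc_aee")) {
    list(change = n_days * aee$estimate,
         interval = n_days * aee$interval, n_days = n_days)
  } else {
    list(change = n_days * as.numeric(aee),
         interval = c(NA_real_, NA_real_), n_days = n_days)
  }
}

#' Mean daily crime counts per zip-code area
#'
#' Descriptive spatial summary: for each named day set (for instance the
#' exposed and control days of each experiment) and each zip-code area,
#' the total incident count on those days divided by the number of days.
#' Areas with no incidents appear with mean 0.
#'
#' @param crimes incident data frame with columns \code{date} and
#'   \code{zip_area} (see \code{\link{read_crimes}}); rows with missing
#'   zip are dropped.
#' @param day_sets named list of \code{Date} vectors.
#' @param areas optional vector of area labels to report (default: all
#'   observed).
#' @return Data frame: \code{set}, \code{zip_area}, \code{mean_daily},
#'   \code{n_days}.
#' @export
spatial_summary <- function(crimes, day_sets, areas = NULL) {
  stopifnot(length(day_sets) >= 1L, !is.null(names(day_sets)))
  crimes <- crimes[!is.na(crimes$zip_area), , drop = FALSE]
  if (is.null(areas)) areas <- sort(unique(crimes$zip_area))
  out <- lapply(names(day_sets), function(nm) {
    days <- day_sets[[nm]]
    if (!length(days)) {
      stop("spatial_summary: empty day set '", nm, "'", call. = FALSE)
    }
    sub <- crimes[crimes$date %in% days, , drop = FALSE]
    counts <- table(factor(sub$zip_area, levels = areas))
    data.frame(set = nm, zip_area = areas,
               mean_daily = as.numeric(counts) / length(days),
               n_days = length(days), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
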