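#' Define one hypothetical experiment
#'
#' An experiment segments the study days by exposure variable (heat-index
#' class or rainfall occurrence) and fixes the threshold rule, the
#' propensity-score model and the outcome model used to reconstruct a
#' randomized comparison.
#'
#' @param name experiment label.
#' @param exposure_var \code{"heat_index"} or \code{"prcp"}.
#' @param class_low,class_high heat-index class bounds in degC; the class
#'   is the half-open interval (class_low, class_high] except that
#'   \code{class_low} is inclusive for the lowest class.  Ignored for the
#'   rain experiment.
#' @param low_inclusive include \code{class_low} itself in the class.
#' @param threshold exposure cut in degC; \code{NULL} (default) means
#'   "compute as the in-class mean heat index".  Rain always uses 0 mm.
#' @param ps_formula one-sided formula for the propensity model.
#' @param outcome_formula one-sided formula for the per-arm outcome model.
#' @return An object of class \code{wc_experiment}.
#' @export
experiment_spec <- function(name, exposure_var = c("heat_index", "prcp"),
                            class_low = NA_real_, class_high = NA_real_,
                            low_inclusive = FALSE, threshold = NULL,
                            ps_formula = ~1, outcome_formula = ~1) {
  exposure_var <- match.arg(exposure_var)
  if (exposure_var == "heat_index") {
    stopifnot(is.finite(class_low), is.finite(class_high),
              class_low < class_high)
    if (!is.null(threshold) &&
        (threshold < class_low || threshold > class_high)) {
      stop("experiment_spec: threshold outside class bounds", call. = FALSE)
    }
  }
  structure(list(name = name, exposure_var = exposure_var,
                 class_low = class_low, class_high = class_high,
                 low_inclusive = low_inclusive, threshold = threshold,
                 ps_formula = ps_formula, outcome_formula = outcome_formula),
            class = "wc_experiment")
}

#' The four Boston hypothetical experiments
#'
#' Catalog of the Negative ([-18, 0] degC), Mild ((0, 24] degC) and High
#' ((24, 35] degC) heat-index experiments plus the rainfall experiment,
#' with the selected propensity-score and outcome models for each.
#' By default each heat experiment's exposure threshold is the in-class
#' mean heat index; \code{pin_thresholds = TRUE} pins the printed rounded
#' cuts (-4, 12, 27 degC) instead.
#'
#' @param pin_thresholds use the rounded thresholds -4/12/27 degC.
#' @return Named list of \code{wc_experiment} objects.
#' @export
boston_experiments <- function(pin_thresholds = FALSE) {
  thr <- function(x) if (pin_thresholds) x else NULL
  list(
    NegativeHI = experiment_spec(
      "NegativeHI", "heat_index", -18, 0, low_inclusive = TRUE,
      threshold = thr(-4),
      ps_formula = ~ Winter + Fall + MidDayMonth + Wind + Rain,
      outcome_formula = ~ FirstDayMonth + MidDayMonth),
    MildHI = experiment_spec(
      "MildHI", "heat_index", 0, 24, threshold = thr(12),
      ps_formula = ~ Winter + Spring + Summer + LastDayMonth + Rain +
        Wind:Rain + Snow + Events,
      outcome_formula = ~ Friday + Weekend + FirstDayMonth + MidDayMonth +
        Wind:Rain),
    HighHI = experiment_spec(
      "HighHI", "heat_index", 24, 35, threshold = thr(27),
      ps_formula = ~ MidDayMonth + Wind,
      outcome_formula = ~ Weekend),
    Rain = experiment_spec(
      "Rain", "prcp",
      ps_formula = ~ Winter + Spring + Wind + Snow + HeatIndex +
        Wind:HeatIndex + Events,
      outcome_formula = ~ Friday + Weekend + FirstDayMonth + Snow + HeatIndex)
  )
}

in_class <- function(z, spec) {
  if (spec$exposure_var != "heat_index") return(rep(TRUE, length(z)))
  lo <- if (spec$low_inclusive) z >= spec$class_low else z > spec$class_low
  lo & z <= spec$class_high
}

#' Exposure threshold for an experiment
#'
#' Heat experiments use the arithmetic mean heat index over the in-class
#' days (unless the spec pins a value); the rain experiment's threshold is
#' 0 mm by definition.
#'
#' @param study study table.
#' @param spec \code{wc_experiment}.
#' @return Threshold on the exposure scale.
#' @export
compute_threshold <- function(study, spec) {
  if (spec$exposure_var == "prcp") return(0)
  if (!is.null(spec$threshold)) return(spec$threshold)
  z <- study$heat_index_c[in_class(study$heat_index_c, spec)]
  if (!length(z)) {
    stop("compute_threshold: no days in class for ", spec$name, call. = FALSE)
  }
  mean(z)
}

#' Assign exposure arms within an experiment
#'
#' Heat experiments: days outside the class are excluded; in-class days
#' with heat index strictly above the threshold are exposed, the rest are
#' controls (ties go to control).  Rain experiment: days with positive
#' precipitation are exposed (rainy), dry days are controls.
#'
#' @param study study table.
#' @param spec \code{wc_experiment}.
#' @param threshold optional pre-computed threshold; default
#'   \code{\link{compute_threshold}}.
#' @return Data frame: \code{date}, \code{experiment}, \code{arm}
#'   (exposed/control/excluded), \code{Z}, \code{T}.
#' @export
assign_arms <- function(study, spec, threshold = NULL) {
  if (is.null(threshold)) threshold <- compute_threshold(study, spec)
  z <- if (spec$exposure_var == "prcp") study$prcp_mm else study$heat_index_c
  arm <- rep("excluded", nrow(study))
  inside <- in_class(z, spec)
  arm[inside] <- ifelse(z[inside] > threshold, "exposed", "control")
  data.frame(date = study$date, experiment = spec$name, arm = arm,
             Z = z, T = threshold, stringsAsFactors = FALSE)
}

#' Named exposure subgroup of a day
#'
#' Descriptive labels for the six heat subgroups and the two rain
#' subgroups, using the rounded thresholds (-4, 12, 27 degC by default).
#'
#' @param z heat index in degC, or precipitation in mm when
#'   \code{exposure_var = "prcp"}.
#' @param exposure_var \code{"heat_index"} or \code{"prcp"}.
#' @param cuts heat thresholds for the Negative, Mild and High classes.
#' @return Character vector of subgroup labels (\code{NA} outside all
#'   classes).
#' @export
exposure_subgroup <- function(z, exposure_var = c("heat_index", "prcp"),
                              cuts = c(-4, 12, 27)) {
  exposure_var <- match.arg(exposure_var)
  if (exposure_var == "prcp") {
    return(ifelse(z > 0, "Rainy (PRCP > 0 mm)", "Dry (PRCP = 0 mm)"))
  }
  out <- rep(NA_character_, length(z))
  out[z >= -18 & z <= cuts[1]] <- "Extremely cold (HI <= -4 °C)"
  out[z > cuts[1] & z <= 0] <- "Very cold (-4 < HI < 0 °C)"
  out[z > 0 & z <= cuts[2]] <- "Cold (0 < HI <= 12 °C)"
  out[z > cuts[2] & z <= 24] <- "Temperate (12 < HI < 24 °C)"
  out[z > 24 & z <= cuts[3]] <- "Very hot (24 < HI <= 27 °C)"
  out[z > cuts[3] & z <= 35] <- "Extremely hot (27 °C < HI)"
  out
}
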