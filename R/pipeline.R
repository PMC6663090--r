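#' Build a run configuration
#'
#' A run configuration bundles the inputs and settings for the
#' end-to-end pipeline: the study table (or the raw CSV paths to build
#' it from), the experiment catalog, matching and MCMC settings, the
#' imputation count, and one global seed that fans out deterministically
#' to every stage.
#'
#' @param study pre-built study table (takes precedence over paths).
#' @param weather_path,crime_path raw CSV paths (used when \code{study}
#'   is \code{NULL}).
#' @param weather_map,crime_map column maps for the raw CSVs.
#' @param experiments named list of \code{\link{experiment_spec}}s.
#' @param outcome outcome column to analyze.
#' @param caliper logit-scale caliper (\code{NULL} = 0.2 SD default).
#' @param smd_threshold balance threshold: a post-matching absolute SMD
#'   above it triggers a prominent warning (the run continues).
#' @param use_stepwise re-derive each propensity model by stepwise AIC
#'   over \code{ps_candidates} instead of using the shipped formula.
#' @param ps_candidates candidate terms for stepwise selection.
#' @param mcmc MCMC settings (\code{\link{nb_mcmc}}); its seed is
#'   overridden by the fanned-out stage seed.
#' @param imputations number of imputation replications R.
#' @param seed global integer seed.
#' @param outdir output directory for result CSVs (\code{NULL} = none).
#' @param arms_override named list (by experiment) of pre-specified arm
#'   assignments, e.g. from a randomized synthetic design.
#' @return Object of class \code{wc_config}.
#' @export
run_config <- function(study = NULL, weather_path = NULL, crime_path = NULL,
                       weather_map = weather_column_map(),
                       crime_map = crime_column_map(),
                       experiments = boston_experiments(),
                       outcome = "violent",
                       caliper = NULL, smd_threshold = 0.1,
                       use_stepwise = FALSE, ps_candidates = NULL,
                       mcmc = nb_mcmc(), imputations = 10000L,
                       seed = 1L, outdir = NULL, arms_override = NULL) {
  if (is.null(study) && (is.null(weather_path) || is.null(crime_path))) {
    stop("run_config: supply a study table or both input paths",
         call. = FALSE)
  }
  if (!is.null(weather_path) && !file.exists(weather_path)) {
    stop("run_config: weather_path does not exist: ", weather_path,
         call. = FALSE)
  }
  if (!is.null(crime_path) && !file.exists(crime_path)) {
    stop("run_config: crime_path does not exist: ", crime_path,
         call. = FALSE)
  }
  structure(as.list(environment()), class = "wc_config")
}

#' Read a run configuration from YAML
#'
#' Formulas are given as strings (e.g. \code{"~ Winter + Wind"});
#' experiments omitted from the file default to the Boston catalog.
#'
#' @param path YAML file path.
#' @return \code{wc_config}.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  experiments <- boston_experiments(
    pin_thresholds = isTRUE(y$pin_thresholds))
  if (!is.null(y$experiments)) {
    experiments <- lapply(y$experiments, function(e) {
      experiment_spec(
        name = e$name,
        exposure_var = e$exposure_var %||% "heat_index",
        class_low = e$class_low %||% NA_real_,
        class_high = e$class_high %||% NA_real_,
        low_inclusive = isTRUE(e$low_inclusive),
        threshold = e$threshold,
        ps_formula = stats::as.formula(e$ps_formula %||% "~1"),
        outcome_formula = stats::as.formula(e$outcome_formula %||% "~1"))
    })
    names(experiments) <- vapply(experiments, `[[`, character(1), "name")
  }
  mc <- nb_mcmc(iterations = y$mcmc$iterations %||% 20000,
                burnin = y$mcmc$burnin %||% 10000,
                chains = y$mcmc$chains %||% 4)
  run_config(weather_path = y$weather_path, crime_path = y$crime_path,
             experiments = experiments,
             outcome = y$outcome %||% "violent",
             caliper = y$caliper,
             smd_threshold = y$smd_threshold %||% 0.1,
             mcmc = mc,
             imputations = y$imputations %||% 10000L,
             seed = y$seed %||% 1L,
             outdir = y$outdir)
}

load_study <- function(config) {
  if (!is.null(config$study)) return(config$study)
  weather <- read_weather(config$weather_path, config$weather_map)
  crimes <- read_crimes(config$crime_path, config$crime_map)
  build_study_table(weather, crimes)
}

#' Run one hypothetical experiment end to end
#'
#' Executes the stages in order: study-table preparation, exposure
#' assignment, the outcome-blind design stage (propensity estimation,
#' overlap trimming, caliper matching, balance diagnostics), the
#' per-arm Bayesian NB outcome fits, and the potential-outcome
#' imputation that yields the AEE posterior.  The design stage operates
#' on a table from which the outcome columns are physically absent, and
#' completes before any outcome column is read.
#'
#' @param config \code{\link{run_config}}.
#' @param name experiment name in the catalog.
#' @param study optional pre-loaded study table (avoids re-reading).
#' @return Result bundle: arms, propensity, matched sample, balance,
#'   per-arm fits, AEE posterior, naive difference-in-means, log lines.
#' @export
run_experiment <- function(config, name, study = NULL) {
  stopifnot(inherits(config, "wc_config"))
  spec <- config$experiments[[name]]
  if (is.null(spec)) {
    stop("run_experiment: unknown experiment '", name, "'", call. = FALSE)
  }
  k <- match(name, names(config$experiments))
  log <- character(0)
  say <- function(stage, fmt, ...) {
    line <- sprintf("[%s] %s", stage, sprintf(fmt, ...))
    log <<- c(log, line)
    message(line)
  }
  wrap <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[%s:%s] %s", name, stage, conditionMessage(e)),
           call. = FALSE)
    })
  }

  study <- wrap("prepare", study %||% load_study(config))
  say("prepare", "%s: study table with %d days", name, nrow(study))

  threshold <- wrap("exposure", compute_threshold(study, spec))
  arms <- if (!is.null(config$arms_override[[name]])) {
    config$arms_override[[name]]
  } else {
    wrap("exposure", assign_arms(study, spec, threshold))
  }
  say("exposure", "threshold = %.3f; %d exposed, %d control, %d excluded",
      threshold, sum(arms$arm == "exposed"), sum(arms$arm == "control"),
      sum(arms$arm == "excluded"))

  design <- wrap("design", design_table(study, arms))
  ps_formula <- if (isTRUE(config$use_stepwise)) {
    wrap("design", stepwise_aic(
      design, config$ps_candidates %||%
        attr(stats::terms(spec$ps_formula), "term.labels")))
  } else {
    spec$ps_formula
  }
  ps <- wrap("design", estimate_propensity(design, ps_formula))
  trim <- wrap("design", trim_overlap(ps))
  say("design", "propensity model %s; %d outlying day(s) trimmed",
      paste(deparse(ps_formula), collapse = " "), nrow(trim$discarded))
  matched <- wrap("design", match_caliper(
    ps, keep = trim$keep, caliper = config$caliper,
    seed = child_seed(config$seed, 10 + k)))
  say("design", "matched %d pairs (caliper %.4f), %d unmatched exposed",
      nrow(matched$pairs), matched$caliper,
      sum(matched$discarded$arm == "exposed"))
  # the exposure variable itself is not a background covariate
  bal_covs <- setdiff(intersect(covariate_names(), names(design)),
                      if (spec$exposure_var == "heat_index") "HeatIndex"
                      else "Rain")
  balance <- wrap("design", balance_smd(design, bal_covs, matched = matched))
  worst <- max(abs(balance$smd_after), na.rm = TRUE)
  if (is.finite(worst) && worst > config$smd_threshold) {
    warning(sprintf(
      "[%s] post-matching imbalance: max |SMD| = %.3f exceeds %.2f",
      name, worst, config$smd_threshold), immediate. = TRUE)
  }
  say("design", "balance: max |SMD| after matching = %.3f", worst)
  if (nrow(matched$pairs) == 0L) {
    stop(sprintf("[%s:design] no matched pairs", name), call. = FALSE)
  }

  # analysis stage: outcomes are read only from here on
  m_dates <- c(matched$pairs$exposed_date, matched$pairs$control_date)
  m_arm <- rep(c("exposed", "control"), each = nrow(matched$pairs))
  mdata <- study[match(m_dates, study$date), , drop = FALSE]
  mdata$arm <- m_arm
  rownames(mdata) <- NULL

  fit_arm <- function(arm_name, offset) {
    sp <- nb_model_spec(
      outcome = config$outcome, formula = spec$outcome_formula,
      mcmc = nb_mcmc(config$mcmc$iterations, config$mcmc$burnin,
                     config$mcmc$chains,
                     seed = child_seed(config$seed, offset + k)))
    fit_outcome_nb(mdata[mdata$arm == arm_name, , drop = FALSE], sp)
  }
  fit_exposed <- wrap("outcome", fit_arm("exposed", 20))
  fit_control <- wrap("outcome", fit_arm("control", 40))
  say("outcome", "per-arm NB fits: max split-Rhat = %.3f (sampler: %s)",
      max(fit_exposed$rhat, fit_control$rhat), fit_exposed$method)

  imp <- wrap("aee", impute_potential_outcomes(
    mdata, fit_exposed, fit_control, R = config$imputations,
    seed = child_seed(config$seed, 60 + k)))
  aee <- wrap("aee", compute_aee(imp))
  say("aee", "AEE = %.3f [%.3f; %.3f], N = %d matched days",
      aee$estimate, aee$interval[1], aee$interval[2], aee$N)

  # naive observed difference in means over the unmatched arms (reporting)
  obs <- study[[config$outcome]][match(arms$date, study$date)]
  naive <- mean(obs[arms$arm == "exposed"]) - mean(obs[arms$arm == "control"])

  bundle <- list(experiment = name, threshold = threshold, arms = arms,
                 propensity = ps, trim = trim, matched = matched,
                 balance = balance, fit_exposed = fit_exposed,
                 fit_control = fit_control, imputations = imp, aee = aee,
                 naive_estimate = naive, log = log, seed = config$seed)
  if (!is.null(config$outdir)) write_bundle(bundle, config$outdir)
  bundle
}

write_bundle <- function(bundle, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  pre <- file.path(outdir, bundle$experiment)
  utils::write.csv(bundle$arms, paste0(pre, "_arms.csv"), row.names = FALSE)
  utils::write.csv(bundle$matched$pairs, paste0(pre, "_pairs.csv"),
                   row.names = FALSE)
  utils::write.csv(rbind(bundle$trim$discarded, bundle$matched$discarded),
                   paste0(pre, "_discarded.csv"), row.names = FALSE)
  utils::write.csv(bundle$balance, paste0(pre, "_balance.csv"),
                   row.names = FALSE)
  res <- data.frame(outcome = bundle$aee$outcome,
                    n_matched = bundle$aee$N,
                    aee = bundle$aee$estimate,
                    lower_2.5 = bundle$aee$interval[1],
                    upper_97.5 = bundle$aee$interval[2],
                    naive_diff = bundle$naive_estimate,
                    seed = bundle$seed)
  utils::write.csv(res, paste0(pre, "_aee.csv"), row.names = FALSE)
  diag <- data.frame(
    parameter = rep(names(bundle$fit_exposed$rhat), 2),
    arm = rep(c("exposed", "control"),
              each = length(bundle$fit_exposed$rhat)),
    rhat = c(bundle$fit_exposed$rhat, bundle$fit_control$rhat),
    ess = c(bundle$fit_exposed$ess, bundle$fit_control$ess))
  utils::write.csv(diag, paste0(pre, "_diagnostics.csv"), row.names = FALSE)
  writeLines(bundle$log, paste0(pre, "_log.txt"))
  invisible(NULL)
}

#' Run every experiment in the catalog
#'
#' Failures are isolated per experiment: an error in one experiment is
#' recorded in its slot and the remaining experiments still run.
#'
#' @param config \code{\link{run_config}}.
#' @return Named list of result bundles (or \code{try-error}s).
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "wc_config"))
  if (!length(config$experiments)) {
    stop("run_all: empty experiment catalog", call. = FALSE)
  }
  study <- load_study(config)
  out <- lapply(names(config$experiments), function(nm) {
    tryCatch(run_experiment(config, nm, study = study),
             error = function(e) {
               warning("experiment ", nm, " failed: ", conditionMessage(e),
                       immediate. = TRUE)
               structure(list(message = conditionMessage(e)),
                         class = "wc_failed")
             })
  })
  names(out) <- names(config$experiments)
  out
}
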