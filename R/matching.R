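#' Outcome-blind design table
#'
#' The design stage must never see the outcome.  This view joins the
#' study covariates with the arm assignment for one experiment, keeps
#' only non-excluded days, and physically drops every outcome column.
#'
#' @param study study table.
#' @param arms arm assignments from \code{\link{assign_arms}}.
#' @return Data frame: \code{date}, \code{exposed} (0/1), covariates.
#' @export
design_table <- function(study, arms) {
  keep <- arms$arm != "excluded"
  idx <- match(arms$date[keep], study$date)
  covs <- intersect(covariate_names(), names(study))
  out <- cbind(
    data.frame(date = arms$date[keep],
               exposed = as.integer(arms$arm[keep] == "exposed")),
    study[idx, covs, drop = FALSE]
  )
  rownames(out) <- NULL
  out
}

drop_degenerate_terms <- function(formula, data) {
  terms_all <- attr(stats::terms(formula), "term.labels")
  if (!length(terms_all)) return(formula)
  keep <- vapply(terms_all, function(tm) {
    vars <- all.vars(stats::reformulate(tm))
    all(vapply(vars, function(v) length(unique(data[[v]])) > 1L, logical(1)))
  }, logical(1))
  if (all(keep)) return(formula)
  warning("degenerate (constant) term(s) dropped from propensity model: ",
          paste(terms_all[!keep], collapse = ", "))
  if (!any(keep)) return(~1)
  stats::reformulate(terms_all[keep])
}

#' Estimate the propensity score
#'
#' Maximum-likelihood logistic regression of the exposure indicator on
#' the background covariates.  Constant covariates are dropped with a
#' warning; perfect separation is an error (reduce the formula).
#'
#' @param design outcome-blind table from \code{\link{design_table}}.
#' @param formula one-sided covariate formula, e.g. \code{~ Winter + Wind}.
#' @return Object of class \code{wc_propensity}: \code{scores} (one per
#'   design row, in (0,1)), \code{fit}, \code{formula}.
#' @export
estimate_propensity <- function(design, formula) {
  if (!all(c(0, 1) %in% design$exposed)) {
    stop("estimate_propensity: need at least one day per arm", call. = FALSE)
  }
  formula <- drop_degenerate_terms(formula, design)
  full <- stats::update(formula, exposed ~ .)
  fit <- stats::glm(full, family = stats::binomial(), data = design)
  # a perfectly separating model fits every day exactly: no MLE exists
  if (fit$deviance < 1e-6 &&
      length(attr(stats::terms(formula), "term.labels"))) {
    stop("estimate_propensity: perfect separation; reduce the formula",
         call. = FALSE)
  }
  scores <- as.numeric(stats::fitted(fit))
  eps <- 1e-12
  scores <- pmin(pmax(scores, eps), 1 - eps)
  structure(list(scores = scores, fit = fit, formula = formula,
                 coefficients = stats::coef(fit), date = design$date,
                 exposed = design$exposed),
            class = "wc_propensity")
}

#' Bidirectional stepwise AIC selection of the propensity model
#'
#' Starts from the intercept-only logistic model and steps in both
#' directions over the candidate terms (main effects and declared
#' interactions), returning the AIC-minimizing formula.  Deterministic
#' given the candidate ordering.
#'
#' @param design outcome-blind design table.
#' @param candidates character vector of candidate terms, e.g.
#'   \code{c("Winter", "Wind", "Wind:Rain")}.
#' @return One-sided formula of the selected model.
#' @export
stepwise_aic <- function(design, candidates) {
  if (!length(candidates)) return(~1)
  upper <- stats::reformulate(unique(candidates))
  upper <- drop_degenerate_terms(upper, design)
  null_fit <- stats::glm(exposed ~ 1, family = stats::binomial(),
                         data = design)
  sel <- stats::step(null_fit,
                     scope = list(lower = ~1,
                                  upper = stats::update(upper, exposed ~ .)),
                     direction = "both", trace = 0)
  labs <- attr(stats::terms(sel), "term.labels")
  if (!length(labs)) ~1 else stats::reformulate(labs)
}

#' Trim non-overlapping propensity scores
#'
#' Discards "outlying days": controls whose estimated score falls outside
#' the range of the exposed days' scores, and vice versa.  The two range
#' rules are applied once, to the original score ranges, matching the
#' usual overlap-assessment step of a design stage.
#'
#' @param ps \code{wc_propensity}.
#' @return List: \code{keep} (logical per design row), \code{discarded}
#'   (data frame date/arm/reason).
#' @export
trim_overlap <- function(ps) {
  e <- ps$scores
  w <- ps$exposed
  if (!any(w == 1) || !any(w == 0)) {
    stop("trim_overlap: need both arms nonempty", call. = FALSE)
  }
  r_exp <- range(e[w == 1])
  r_ctl <- range(e[w == 0])
  keep <- ifelse(w == 1, e >= r_ctl[1] & e <= r_ctl[2],
                 e >= r_exp[1] & e <= r_exp[2])
  if (!any(keep & w == 1) || !any(keep & w == 0)) {
    stop("trim_overlap: trimming emptied an arm", call. = FALSE)
  }
  discarded <- data.frame(
    date = ps$date[!keep],
    arm = ifelse(w[!keep] == 1, "exposed", "control"),
    reason = rep("outlying", sum(!keep)), stringsAsFactors = FALSE)
  list(keep = keep, discarded = discarded)
}

#' Default caliper width
#'
#' 0.2 standard deviations of the logit propensity score (the
#' Rosenbaum-Rubin convention), computed over the supplied scores.
#'
#' @param scores propensity scores in (0,1).
#' @param mult multiplier (default 0.2).
#' @return Caliper on the logit scale.
#' @export
default_caliper <- function(scores, mult = 0.2) {
  mult * stats::sd(logit(scores))
}

#' One-to-one propensity-score matching with caliper
#'
#' Greedy nearest-neighbor matching without replacement on the logit
#' score scale.  Exposed days are processed in descending score order;
#' each takes the nearest remaining control within the caliper
#' (equidistant candidates broken by a seeded draw).  Exposed days with
#' no admissible control are discarded and logged as unmatched.
#'
#' @param ps \code{wc_propensity}.
#' @param keep logical vector from \code{\link{trim_overlap}} (default:
#'   keep all).
#' @param caliper maximum logit-score distance within a pair; default
#'   \code{\link{default_caliper}} of the retained scores.
#' @param seed integer seed for tie-breaking.
#' @return Object of class \code{wc_matched}: \code{pairs} (data frame
#'   exposed_date/control_date/distance), \code{discarded}, \code{caliper}.
#' @export
match_caliper <- function(ps, keep = NULL, caliper = NULL, seed = 1L) {
  if (is.null(keep)) keep <- rep(TRUE, length(ps$scores))
  l <- logit(ps$scores)
  if (is.null(caliper)) caliper <- default_caliper(ps$scores[keep])
  if (!is.finite(caliper) || caliper <= 0) {
    stop("match_caliper: caliper must be positive", call. = FALSE)
  }
  exp_idx <- which(keep & ps$exposed == 1)
  ctl_idx <- which(keep & ps$exposed == 0)
  exp_idx <- exp_idx[order(l[exp_idx], decreasing = TRUE)]
  avail <- rep(TRUE, length(ctl_idx))
  pairs <- vector("list", length(exp_idx))
  unmatched <- integer(0)
  set.seed(seed)
  for (k in seq_along(exp_idx)) {
    i <- exp_idx[k]
    d <- abs(l[ctl_idx] - l[i])
    d[!avail] <- Inf
    j <- which(d <= caliper + 1e-15)
    if (!length(j)) {
      unmatched <- c(unmatched, i)
      next
    }
    best <- j[d[j] <= min(d[j]) + 1e-12]
    pick <- if (length(best) > 1L) best[sample.int(length(best), 1L)] else best
    avail[pick] <- FALSE
    pairs[[k]] <- data.frame(exposed_date = ps$date[i],
                             control_date = ps$date[ctl_idx[pick]],
                             distance = d[pick])
  }
  pairs <- do.call(rbind, pairs[!vapply(pairs, is.null, logical(1))])
  if (is.null(pairs)) {
    pairs <- data.frame(exposed_date = ps$date[0], control_date = ps$date[0],
                        distance = numeric(0))
  }
  leftover <- ctl_idx[avail]
  n_d <- length(unmatched) + length(leftover)
  discarded <- data.frame(
    date = c(ps$date[unmatched], ps$date[leftover]),
    arm = c(rep("exposed", length(unmatched)),
            rep("control", length(leftover))),
    reason = rep("unmatched", n_d), stringsAsFactors = FALSE)
  structure(list(pairs = pairs, discarded = discarded, caliper = caliper,
                 seed = seed),
            class = "wc_matched")
}

#' @export
print.wc_matched <- function(x, ...) {
  cat("Matched sample: ", nrow(x$pairs), " pairs, ",
      sum(x$discarded$arm == "exposed"),
      " unmatched exposed day(s), caliper = ",
      signif(x$caliper, 4), " (logit scale)\n", sep = "")
  invisible(x)
}

#' Covariate balance as standardized mean differences
#'
#' SMD = (mean exposed - mean control) / pooled SD, with the pooled SD
#' computed once on the pre-matching sample and reused after matching so
#' that the before/after columns share a scale.  A zero pooled SD yields
#' \code{NaN} (flagged, not an error).
#'
#' @param design outcome-blind design table.
#' @param covariates covariate column names to diagnose.
#' @param matched optional \code{wc_matched}; when supplied the
#'   after-matching column is computed on its pairs.
#' @return Data frame of class \code{wc_balance}: covariate, smd_before,
#'   smd_after (NA when no matched sample given).
#' @export
balance_smd <- function(design, covariates = NULL, matched = NULL) {
  if (is.null(covariates)) {
    covariates <- intersect(covariate_names(), names(design))
  }
  smd_on <- function(rows_e, rows_c, pooled_sd) {
    vapply(covariates, function(v) {
      d <- mean(design[[v]][rows_e]) - mean(design[[v]][rows_c])
      d / pooled_sd[[v]]
    }, numeric(1))
  }
  all_e <- which(design$exposed == 1)
  all_c <- which(design$exposed == 0)
  pooled_sd <- vapply(covariates, function(v) {
    sqrt((stats::var(design[[v]][all_e]) + stats::var(design[[v]][all_c])) / 2)
  }, numeric(1))
  before <- smd_on(all_e, all_c, pooled_sd)
  after <- rep(NA_real_, length(covariates))
  if (!is.null(matched) && nrow(matched$pairs)) {
    m_e <- match(matched$pairs$exposed_date, design$date)
    m_c <- match(matched$pairs$control_date, design$date)
    after <- smd_on(m_e, m_c, pooled_sd)
  }
  out <- data.frame(covariate = covariates, smd_before = unname(before),
                    smd_after = unname(after), stringsAsFactors = FALSE)
  class(out) <- c("wc_balance", "data.frame")
  out
}
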