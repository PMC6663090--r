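# Pareto-smoothed importance sampling LOO, built from the generalized
# Pareto tail fit of Zhang & Stephens (2009).

gpd_fit <- function(x) {
  # x: positive exceedances; profile-likelihood fit with a weak prior
  # pulling the shape toward 1/2
  x <- sort(x)
  n <- length(x)
  prior_bs <- 3
  m <- 30L + floor(sqrt(n))
  jj <- seq_len(m)
  xstar <- x[max(1L, floor(n / 4 + 0.5))]
  theta <- 1 / x[n] + (1 - sqrt(m / (jj - 0.5))) / (prior_bs * xstar)
  # Zhang-Stephens profile: given theta, the shape MLE is
  # -mean(log1p(-theta x)); the PSIS tail shape is its negative
  k_j <- -vapply(theta, function(t) mean(log1p(-t * x)), numeric(1))
  l_j <- n * (log(theta / k_j) + k_j - 1)
  w <- exp(l_j - max(l_j))
  w <- w / sum(w)
  theta_hat <- sum(theta * w)
  xi <- mean(log1p(-theta_hat * x))
  sigma <- -xi / theta_hat
  xi <- (n * xi + 5) / (n + 10)
  list(k = xi, sigma = sigma)
}

qgpd <- function(p, k, sigma) {
  if (abs(k) < 1e-12) return(-sigma * log1p(-p))
  sigma * expm1(-k * log1p(-p)) / k
}

# smooth one vector of log importance ratios; returns the smoothed log
# weights and the Pareto k-hat diagnostic
psis_smooth <- function(lw) {
  S <- length(lw)
  lw <- lw - max(lw)
  m <- ceiling(min(0.2 * S, 3 * sqrt(S)))
  if (m < 5) return(list(lw = lw, k = 0))
  ord <- order(lw)
  tail_ids <- ord[(S - m + 1):S]
  cutoff <- lw[ord[S - m]]
  exceed <- exp(lw[tail_ids]) - exp(cutoff)
  if (all(exceed <= 0)) return(list(lw = lw, k = 0))
  fit <- gpd_fit(exceed[exceed > 0])
  if (!is.finite(fit$k)) return(list(lw = lw, k = Inf))
  # replace tail by expected order statistics of the fitted GPD
  p <- (seq_len(m) - 0.5) / m
  repl <- log(exp(cutoff) + qgpd(p, fit$k, fit$sigma))
  repl <- pmin(repl, 0)  # truncate at the raw maximum (lw is max-centered)
  lw[tail_ids[order(lw[tail_ids])]] <- repl
  list(lw = lw - max(lw), k = fit$k)
}

log_sum_exp <- function(x) {
  mx <- max(x)
  mx + log(sum(exp(x - mx)))
}

#' PSIS leave-one-out expected log predictive density
#'
#' Computes the pointwise LOO elpd from a draws-by-observations
#' log-likelihood matrix by Pareto-smoothed importance sampling, with
#' the tail Pareto shape diagnostic k-hat per observation.
#'
#' @param log_lik matrix, draws x observations.
#' @return List: \code{elpd_i}, \code{k}, \code{elpd} (sum).
#' @export
psis_loo <- function(log_lik) {
  n <- ncol(log_lik)
  elpd_i <- numeric(n)
  k <- numeric(n)
  for (i in seq_len(n)) {
    sm <- psis_smooth(-log_lik[, i])
    k[i] <- sm$k
    elpd_i[i] <- log_sum_exp(sm$lw + log_lik[, i]) - log_sum_exp(sm$lw)
  }
  list(elpd_i = elpd_i, k = k, elpd = sum(elpd_i))
}

# exact leave-one-out refit for observations whose importance ratios are
# unreliable (k-hat > threshold)
exact_loo_point <- function(data, spec, i, refit_mcmc) {
  spec_small <- spec
  spec_small$mcmc <- refit_mcmc
  fit_i <- fit_outcome_nb(data[-i, , drop = FALSE], spec_small)
  mu <- nb_mu_draws(fit_i, data[i, , drop = FALSE])
  phi <- fit_i$draws[, "phi"]
  y_i <- data[[spec$outcome]][i]
  ll <- stats::dnbinom(y_i, size = phi, mu = drop(mu), log = TRUE)
  log_sum_exp(ll) - log(length(ll))
}

#' Select an outcome model by LOO cross-validation
#'
#' Fits each candidate model, scores it by PSIS-LOO elpd, and returns
#' the best.  Observations with Pareto k-hat above \code{k_threshold}
#' fall back to exact leave-one-out refits (logged via message).  Ties
#' are broken toward fewer terms, then input order.
#'
#' @param data arm data frame (outcome + covariates).
#' @param specs list of \code{\link{nb_model_spec}} candidates.
#' @param k_threshold Pareto k-hat above which a point is refit exactly.
#' @return List: \code{spec} (the winner), \code{elpd} (per candidate),
#'   \code{fits}.
#' @export
loo_select <- function(data, specs, k_threshold = 0.7) {
  stopifnot(length(specs) >= 1L)
  if (length(specs) == 1L) {
    return(list(spec = specs[[1L]], elpd = NA_real_, fits = NULL))
  }
  refit_mcmc <- nb_mcmc(iterations = 1200, burnin = 600, chains = 2,
                        seed = specs[[1L]]$mcmc$seed)
  fits <- lapply(specs, function(sp) fit_outcome_nb(data, sp))
  elpd <- vapply(seq_along(specs), function(j) {
    res <- psis_loo(nb_log_lik(fits[[j]]))
    bad <- which(res$k > k_threshold)
    if (length(bad)) {
      message("loo_select: exact refit for ", length(bad),
              " observation(s) with k-hat > ", k_threshold)
      for (i in bad) {
        res$elpd_i[i] <- exact_loo_point(data, specs[[j]], i, refit_mcmc)
      }
    }
    sum(res$elpd_i)
  }, numeric(1))
  n_terms <- vapply(specs, function(sp) {
    length(attr(stats::terms(sp$formula), "term.labels"))
  }, integer(1))
  best <- max(elpd)
  cand <- which(elpd >= best - 1e-8)
  cand <- cand[order(n_terms[cand], cand)]
  list(spec = specs[[cand[1L]]], elpd = elpd, fits = fits)
}
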