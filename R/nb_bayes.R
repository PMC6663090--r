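#' Prior settings for the NB outcome model
#'
#' Weakly informative defaults: intercept N(0, 5), slopes N(0, 2.5) (on
#' standardized continuous covariates), dispersion Half-Cauchy(0, 5).
#'
#' @param intercept_scale,slope_scale,dispersion_scale prior scales.
#' @return List of prior scales.
#' @export
nb_priors <- function(intercept_scale = 5, slope_scale = 2.5,
                      dispersion_scale = 5) {
  list(intercept_scale = intercept_scale, slope_scale = slope_scale,
       dispersion_scale = dispersion_scale)
}

#' MCMC settings
#'
#' Totals across chains: the default 20,000 iterations with 10,000
#' burn-in retains 10,000 parameter draws, split over 4 chains.
#'
#' @param iterations,burnin totals across chains.
#' @param chains number of chains.
#' @param seed integer seed.
#' @return List of MCMC settings.
#' @export
nb_mcmc <- function(iterations = 20000, burnin = 10000, chains = 4,
                    seed = 1L) {
  stopifnot(iterations > burnin, chains >= 1)
  list(iterations = iterations, burnin = burnin, chains = chains,
       seed = as.integer(seed))
}

#' Specify a per-arm NB outcome model
#'
#' @param outcome outcome column name (\code{"violent"},
#'   \code{"aggravated_assault"} or \code{"larceny"}).
#' @param formula one-sided covariate formula.
#' @param priors see \code{\link{nb_priors}}.
#' @param mcmc see \code{\link{nb_mcmc}}.
#' @param standardize standardize continuous covariates before applying
#'   the slope priors (binary columns are left unscaled).
#' @return Object of class \code{wc_nbspec}.
#' @export
nb_model_spec <- function(outcome = "violent", formula = ~1,
                          priors = nb_priors(), mcmc = nb_mcmc(),
                          standardize = TRUE) {
  structure(list(outcome = outcome, formula = formula, priors = priors,
                 mcmc = mcmc, standardize = standardize),
            class = "wc_nbspec")
}

# design matrix with optional standardization of continuous columns;
# scaling computed on first use, reused via the `scaling` argument
nb_design <- function(formula, data, standardize = TRUE, scaling = NULL) {
  X <- stats::model.matrix(formula, data)
  if (!standardize) return(list(X = X, center = NULL, scale = NULL))
  if (is.null(scaling)) {
    cont <- apply(X, 2, function(v) length(unique(v)) > 2L)
    cont[colnames(X) == "(Intercept)"] <- FALSE
    center <- ifelse(cont, colMeans(X), 0)
    scl <- ifelse(cont, apply(X, 2, stats::sd), 1)
    scl[scl == 0] <- 1
  } else {
    center <- scaling$center
    scl <- scaling$scale
  }
  X <- sweep(sweep(X, 2, center, "-"), 2, scl, "/")
  list(X = X, center = center, scale = scl)
}

half_cauchy_log <- function(x, scale) {
  log(2) - log(pi * scale * (1 + (x / scale)^2))
}

# joint log posterior over th = c(beta, log(phi))
nb_log_post <- function(th, y, X, priors) {
  p <- ncol(X)
  beta <- th[seq_len(p)]
  lphi <- th[p + 1L]
  phi <- exp(lphi)
  eta <- drop(X %*% beta)
  eta <- pmin(eta, 30)
  ll <- sum(stats::dnbinom(y, size = phi, mu = exp(eta), log = TRUE))
  lp <- stats::dnorm(beta[1L], 0, priors$intercept_scale, log = TRUE)
  if (p > 1L) {
    lp <- lp + sum(stats::dnorm(beta[-1L], 0, priors$slope_scale, log = TRUE))
  }
  # half-Cauchy on phi, with the log-scale Jacobian
  lp <- lp + half_cauchy_log(phi, priors$dispersion_scale) + lphi
  ll + lp
}

# multivariate-t proposal machinery (df fixed at 7)
rmvt_prop <- function(n, center, L, df = 7) {
  d <- length(center)
  z <- matrix(stats::rnorm(n * d), n, d) %*% t(L)
  g <- sqrt(stats::rchisq(n, df) / df)
  sweep(z / g, 2, center, "+")
}

dmvt_log <- function(th, center, L, df = 7) {
  d <- length(center)
  z <- forwardsolve(L, th - center)
  q <- sum(z^2)
  lgamma((df + d) / 2) - lgamma(df / 2) - (d / 2) * log(df * pi) -
    sum(log(diag(L))) - ((df + d) / 2) * log1p(q / df)
}

nb_init <- function(y, X) {
  p <- ncol(X)
  beta <- rep(0, p)
  lphi <- 0
  fit <- tryCatch(
    suppressWarnings(MASS::glm.nb(y ~ X - 1)),
    error = function(e) NULL)
  if (!is.null(fit) && all(is.finite(stats::coef(fit)))) {
    beta <- unname(stats::coef(fit))
    lphi <- log(max(fit$theta, 1e-3))
  } else {
    fit2 <- tryCatch(
      suppressWarnings(stats::glm.fit(X, y, family = stats::poisson())),
      error = function(e) NULL)
    if (!is.null(fit2) && all(is.finite(fit2$coefficients))) {
      beta <- unname(fit2$coefficients)
    } else {
      beta[1] <- log(mean(y) + 0.1)
    }
  }
  c(beta, lphi)
}

run_chain <- function(lpost, start, L, n_iter, n_burn, seed,
                      method = c("independence", "rwm"), df = 7) {
  method <- match.arg(method)
  set.seed(seed)
  d <- length(start)
  cur <- start
  lp_cur <- lpost(cur)
  if (method == "independence") lq_cur <- dmvt_log(cur, start, L, df)
  out <- matrix(NA_real_, n_iter - n_burn, d)
  acc <- 0L
  rw_scale <- 2.38 / sqrt(d)
  for (s in seq_len(n_iter)) {
    if (method == "independence") {
      prop <- drop(rmvt_prop(1, start, L, df))
      lp_prop <- lpost(prop)
      lq_prop <- dmvt_log(prop, start, L, df)
      lr <- (lp_prop - lq_prop) - (lp_cur - lq_cur)
    } else {
      prop <- cur + rw_scale * drop(rmvt_prop(1, rep(0, d), L, df = 50))
      lp_prop <- lpost(prop)
      lr <- lp_prop - lp_cur
    }
    if (is.finite(lp_prop) && log(stats::runif(1)) < lr) {
      cur <- prop
      lp_cur <- lp_prop
      if (method == "independence") lq_cur <- lq_prop
      acc <- acc + 1L
    }
    if (s > n_burn) out[s - n_burn, ] <- cur
  }
  list(draws = out, accept = acc / n_iter)
}

split_rhat <- function(chains) {
  # chains: list of numeric vectors (one per chain), equal length
  n <- length(chains[[1]])
  half <- floor(n / 2)
  seqs <- unlist(lapply(chains, function(x) {
    list(x[seq_len(half)], x[(n - half + 1):n])
  }), recursive = FALSE)
  m <- length(seqs)
  means <- vapply(seqs, mean, numeric(1))
  vars <- vapply(seqs, stats::var, numeric(1))
  W <- mean(vars)
  B <- half * stats::var(means)
  if (W == 0) return(1)
  sqrt(((half - 1) / half * W + B / half) / W)
}

geyer_ess <- function(x) {
  n <- length(x)
  if (stats::var(x) == 0) return(n)
  rho <- stats::acf(x, lag.max = min(n - 1L, 250L), plot = FALSE,
                    demean = TRUE)$acf[-1]
  # Geyer initial positive sequence on pairs
  s <- 0
  t <- 1
  while (t + 1 <= length(rho)) {
    pair <- rho[t] + rho[t + 1]
    if (pair < 0) break
    s <- s + pair
    t <- t + 2
  }
  max(1, n / (1 + 2 * s))
}

#' Fit a Bayesian negative-binomial outcome model
#'
#' NB2 likelihood (variance mu + mu^2/phi) with log link and the
#' weakly informative priors of \code{\link{nb_priors}}.  Sampling uses
#' an independence Metropolis-Hastings kernel whose proposal is a
#' multivariate-t built from the Laplace approximation at the joint
#' posterior mode of (beta, log phi); if acceptance is poor the sampler
#' falls back to a random-walk kernel with the same covariance.  Each
#' exposure arm is fit independently.  With zero data rows the draws are
#' taken directly from the priors (the exact posterior in that case).
#'
#' @param data data frame holding the outcome column and covariates
#'   (typically one arm of a matched sample).
#' @param spec \code{\link{nb_model_spec}}.
#' @return Object of class \code{wc_nbfit}: \code{draws} (retained draws
#'   x parameters; columns are the design terms then \code{phi}),
#'   \code{rhat}, \code{ess}, \code{accept}, \code{method}, plus the
#'   design metadata needed for prediction.
#' @export
fit_outcome_nb <- function(data, spec) {
  stopifnot(inherits(spec, "wc_nbspec"))
  mc <- spec$mcmc
  n_keep <- mc$iterations - mc$burnin
  if (nrow(data) == 0L) {
    return(nb_prior_fit(spec, n_keep))
  }
  y <- data[[spec$outcome]]
  if (is.null(y)) stop("fit_outcome_nb: no column ", spec$outcome,
                       call. = FALSE)
  if (any(y < 0) || any(y != round(y))) {
    stop("fit_outcome_nb: outcome must be nonnegative integers",
         call. = FALSE)
  }
  if (all(y == 0)) message("fit_outcome_nb: all-zero outcome; fit proceeds")
  des <- nb_design(spec$formula, data, spec$standardize)
  X <- des$X
  p <- ncol(X)
  lpost <- function(th) nb_log_post(th, y, X, spec$priors)
  start <- nb_init(y, X)
  opt <- stats::optim(start, function(th) -lpost(th), method = "BFGS",
                      hessian = TRUE, control = list(maxit = 500))
  H <- opt$hessian
  Sigma <- tryCatch(solve(H), error = function(e) NULL)
  if (is.null(Sigma) || any(!is.finite(Sigma)) ||
      any(diag(Sigma) <= 0)) {
    Sigma <- diag(1e-2, p + 1L)
  }
  Sigma <- (Sigma + t(Sigma)) / 2
  L <- tryCatch(t(chol(1.3 * Sigma)),
                error = function(e) t(chol(1.3 * (Sigma + diag(1e-6, p + 1L)))))
  per_iter <- ceiling(mc$iterations / mc$chains)
  per_burn <- ceiling(mc$burnin / mc$chains)
  run_all <- function(method) {
    lapply(seq_len(mc$chains), function(cid) {
      run_chain(lpost, opt$par, L, per_iter, per_burn,
                seed = child_seed(mc$seed, cid), method = method)
    })
  }
  method <- "independence"
  chains <- run_all(method)
  acc <- vapply(chains, `[[`, numeric(1), "accept")
  if (mean(acc) < 0.10) {
    method <- "rwm"
    chains <- run_all(method)
    acc <- vapply(chains, `[[`, numeric(1), "accept")
  }
  draw_list <- lapply(chains, `[[`, "draws")
  draws <- do.call(rbind, draw_list)
  draws <- draws[seq_len(min(n_keep, nrow(draws))), , drop = FALSE]
  # phi on the natural scale
  draws[, p + 1L] <- exp(draws[, p + 1L])
  colnames(draws) <- c(colnames(X), "phi")
  rhat <- vapply(seq_len(p + 1L), function(j) {
    split_rhat(lapply(draw_list, function(m) m[, j]))
  }, numeric(1))
  ess <- vapply(seq_len(p + 1L), function(j) {
    sum(vapply(draw_list, function(m) geyer_ess(m[, j]), numeric(1)))
  }, numeric(1))
  names(rhat) <- names(ess) <- colnames(draws)
  converged <- all(rhat < 1.05)
  if (!converged) {
    warning("fit_outcome_nb: split-Rhat > 1.05 for ",
            paste(names(rhat)[rhat >= 1.05], collapse = ", "),
            "; treat results with caution")
  }
  structure(list(draws = draws, rhat = rhat, ess = ess,
                 accept = acc, method = method, converged = converged,
                 formula = spec$formula, outcome = spec$outcome,
                 standardize = spec$standardize,
                 scaling = list(center = des$center, scale = des$scale),
                 y = y, X = X, spec = spec),
            class = "wc_nbfit")
}

# prior-only "fit": iid draws from the priors
nb_prior_fit <- function(spec, n_keep) {
  set.seed(spec$mcmc$seed)
  tl <- attr(stats::terms(spec$formula), "term.labels")
  p <- length(tl) + 1L
  pr <- spec$priors
  draws <- cbind(
    stats::rnorm(n_keep, 0, pr$intercept_scale),
    if (p > 1L) matrix(stats::rnorm(n_keep * (p - 1L), 0, pr$slope_scale),
                       n_keep, p - 1L),
    abs(stats::rcauchy(n_keep, 0, pr$dispersion_scale)))
  colnames(draws) <- c("(Intercept)", tl, "phi")
  structure(list(draws = draws, rhat = rep(1, p + 1L), ess = rep(n_keep, p + 1L),
                 accept = 1, method = "prior", converged = TRUE,
                 formula = spec$formula, outcome = spec$outcome,
                 standardize = spec$standardize,
                 scaling = NULL, y = integer(0), X = NULL, spec = spec),
            class = "wc_nbfit")
}

#' @export
print.wc_nbfit <- function(x, ...) {
  cat("Bayesian NB fit (", x$outcome, "): ", nrow(x$draws),
      " draws, sampler = ", x$method,
      ", max split-Rhat = ", signif(max(x$rhat), 4), "\n", sep = "")
  pm <- colMeans(x$draws)
  print(signif(pm, 4))
  invisible(x)
}

#' Posterior draws of the NB mean for new days
#'
#' Applies the fit's stored design (terms and standardization) to new
#' rows and returns the matrix of posterior mean-parameter draws.
#'
#' @param fit \code{wc_nbfit}.
#' @param newdata data frame of covariates.
#' @param draws_idx optional draw indices (default all).
#' @return Matrix, rows = newdata rows, columns = draws.
#' @export
nb_mu_draws <- function(fit, newdata, draws_idx = NULL) {
  des <- nb_design(fit$formula, newdata, fit$standardize, fit$scaling)
  B <- fit$draws[, setdiff(colnames(fit$draws), "phi"), drop = FALSE]
  if (!is.null(draws_idx)) B <- B[draws_idx, , drop = FALSE]
  eta <- des$X %*% t(B)
  exp(pmin(eta, 30))
}

# pointwise log-likelihood matrix (draws x observations)
nb_log_lik <- function(fit, thin_to = 1000L) {
  S <- nrow(fit$draws)
  idx <- if (S > thin_to) round(seq(1, S, length.out = thin_to)) else seq_len(S)
  B <- fit$draws[idx, setdiff(colnames(fit$draws), "phi"), drop = FALSE]
  phi <- fit$draws[idx, "phi"]
  eta <- fit$X %*% t(B)
  mu <- exp(pmin(eta, 30))
  n <- length(fit$y)
  ll <- stats::dnbinom(rep(fit$y, length(idx)),
                       size = rep(phi, each = n), mu = mu, log = TRUE)
  t(matrix(ll, n, length(idx)))
}
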