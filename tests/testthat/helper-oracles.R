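# Independent naive re-implementations used as oracles.  These stay
# deliberately dumb: plain loops, no shared code with the package paths
# they check.

# brute-force application of the two overlap range rules
oracle_trim <- function(scores, exposed) {
  keep <- logical(length(scores))
  e_rng <- c(min(scores[exposed == 1]), max(scores[exposed == 1]))
  c_rng <- c(min(scores[exposed == 0]), max(scores[exposed == 0]))
  for (i in seq_along(scores)) {
    keep[i] <- if (exposed[i] == 1) {
      scores[i] >= c_rng[1] && scores[i] <= c_rng[2]
    } else {
      scores[i] >= e_rng[1] && scores[i] <= e_rng[2]
    }
  }
  keep
}

# greedy 1:1 nearest-neighbor caliper matching on the logit scale,
# exposed in descending score order, seeded tie-break
oracle_greedy_match <- function(scores, exposed, dates, caliper, seed) {
  l <- log(scores / (1 - scores))
  ei <- which(exposed == 1)
  ci <- which(exposed == 0)
  ei <- ei[order(l[ei], decreasing = TRUE)]
  used <- rep(FALSE, length(ci))
  out <- NULL
  set.seed(seed)
  for (i in ei) {
    best_j <- integer(0)
    best_d <- Inf
    for (jj in seq_along(ci)) {
      if (used[jj]) next
      d <- abs(l[ci[jj]] - l[i])
      if (d > caliper + 1e-15) next
      if (d < best_d - 1e-12) {
        best_d <- d
        best_j <- jj
      } else if (d <= best_d + 1e-12) {
        best_j <- c(best_j, jj)
      }
    }
    if (!length(best_j)) next
    pick <- if (length(best_j) > 1L) {
      best_j[sample.int(length(best_j), 1L)]
    } else {
      best_j
    }
    used[pick] <- TRUE
    out <- rbind(out, data.frame(exposed_date = dates[i],
                                 control_date = dates[ci[pick]]))
  }
  out
}

# direct evaluation of the standardized-mean-difference formula with the
# pooled SD taken from the full pre-matching sample
oracle_smd <- function(x, exposed, rows_e = NULL, rows_c = NULL) {
  pooled <- sqrt((var(x[exposed == 1]) + var(x[exposed == 0])) / 2)
  if (is.null(rows_e)) rows_e <- which(exposed == 1)
  if (is.null(rows_c)) rows_c <- which(exposed == 0)
  (mean(x[rows_e]) - mean(x[rows_c])) / pooled
}

# exhaustive all-subsets AIC minimum for a logistic model
oracle_best_aic <- function(design, candidates) {
  best_terms <- character(0)
  best_aic <- stats::AIC(stats::glm(exposed ~ 1, binomial(), design))
  for (k in seq_along(candidates)) {
    combos <- utils::combn(candidates, k, simplify = FALSE)
    for (cc in combos) {
      f <- stats::reformulate(cc, response = "exposed")
      a <- stats::AIC(stats::glm(f, binomial(), design))
      if (a < best_aic - 1e-9) {
        best_aic <- a
        best_terms <- cc
      }
    }
  }
  sort(best_terms)
}

# brute-force per-day incident tally
oracle_tally <- function(dates, buckets, days, bucket) {
  sapply(days, function(d) sum(dates == d & buckets == bucket))
}

# small random design for propensity/matching tests: one continuous
# confounder driving exposure
make_ps_design <- function(n, seed, beta = 1) {
  set.seed(seed)
  x <- rnorm(n)
  w <- rbinom(n, 1, plogis(beta * x))
  if (all(w == 1) || all(w == 0)) w[1:2] <- c(0L, 1L)
  data.frame(date = seq(as.Date("2015-01-01"), by = "day", length.out = n),
             exposed = w, X = x)
}

# reduced-budget settings shared by the slower model-based tests
fast_mcmc <- function(seed = 1L) nb_mcmc(2000, 1000, chains = 2, seed = seed)

run_synth_pipeline <- function(seed, n_days = 600, imputations = 500,
                               tau = 0.2, exposure = "threshold") {
  cfg <- synthetic_config(n_days = n_days, seed = seed, tau = tau,
                          exposure = exposure)
  synth <- generate_synthetic(cfg)
  sp <- synthetic_experiment(cfg)
  rc <- run_config(study = synth$study,
                   experiments = stats::setNames(list(sp), "SynthHI"),
                   mcmc = fast_mcmc(seed), imputations = imputations,
                   seed = seed)
  b <- suppressWarnings(suppressMessages(run_experiment(rc, "SynthHI")))
  matched_dates <- c(b$matched$pairs$exposed_date,
                     b$matched$pairs$control_date)
  list(bundle = b, synth = synth,
       truth = truth_aee(synth, matched_dates))
}
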