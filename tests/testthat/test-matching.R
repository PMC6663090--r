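test_that("propensity scores reduce to cell proportions in saturated cases", {
  d <- data.frame(date = seq(as.Date("2015-01-01"), by = "day",
                             length.out = 20),
                  exposed = rep(c(1L, 0L), each = 10))
  ps <- estimate_propensity(d, ~1)
  expect_equal(ps$scores, rep(0.5, 20), tolerance = 1e-8)

  # one binary covariate: scores are the within-level exposure proportions
  set.seed(2)
  d2 <- data.frame(date = seq(as.Date("2015-01-01"), by = "day",
                              length.out = 200),
                   B = rbinom(200, 1, 0.5))
  d2$exposed <- rbinom(200, 1, ifelse(d2$B == 1, 0.7, 0.3))
  ps2 <- estimate_propensity(d2, ~B)
  for (lev in 0:1) {
    prop <- mean(d2$exposed[d2$B == lev])
    expect_equal(unique(round(ps2$scores[d2$B == lev], 10)), round(prop, 10))
  }
})

test_that("degenerate propensity inputs are caught", {
  d <- make_ps_design(60, seed = 4)
  d$C <- 1  # constant covariate
  expect_warning(ps <- estimate_propensity(d, ~X + C), "degenerate")
  expect_equal(length(ps$scores), 60)
  # perfect separation is an error suggesting formula reduction
  d$S <- ifelse(d$exposed == 1, 1, 0)
  expect_error(suppressWarnings(estimate_propensity(d, ~S)), "separation")
})

test_that("stepwise AIC selection matches exhaustive enumeration", {
  expect_equal(format(stepwise_aic(make_ps_design(50, 1), character(0))), "~1")

  set.seed(9)
  n <- 200
  d <- data.frame(date = seq(as.Date("2014-01-01"), by = "day",
                             length.out = n),
                  A = rnorm(n), B = rnorm(n), C = rbinom(n, 1, 0.5),
                  D = rnorm(n), E = rbinom(n, 1, 0.4))
  d$exposed <- rbinom(n, 1, plogis(1.2 * d$A - 1.5 * d$C))
  sel <- stepwise_aic(d, c("A", "B", "C", "D", "E"))
  expect_setequal(attr(terms(sel), "term.labels"),
                  oracle_best_aic(d, c("A", "B", "C", "D", "E")))

  # a duplicated candidate never enters twice
  sel2 <- stepwise_aic(d, c("A", "A", "C"))
  expect_equal(sum(attr(terms(sel2), "term.labels") == "A"), 1)
})

test_that("overlap trimming applies the two range rules", {
  mk_ps <- function(scores, exposed) {
    structure(list(scores = scores, exposed = exposed,
                   date = seq(as.Date("2015-01-01"), by = "day",
                              length.out = length(scores))),
              class = "wc_propensity")
  }
  # identical ranges: nothing discarded, and the trim is a no-op twice
  ps <- mk_ps(c(0.2, 0.8, 0.2, 0.8), c(1, 1, 0, 0))
  tr <- trim_overlap(ps)
  expect_true(all(tr$keep))
  expect_equal(nrow(tr$discarded), 0)

  # one control below the exposed minimum: exactly that day discarded
  ps2 <- mk_ps(c(0.4, 0.6, 0.1, 0.45, 0.6), c(1, 1, 0, 0, 0))
  tr2 <- trim_overlap(ps2)
  expect_equal(tr2$discarded$date, ps2$date[3])
  expect_equal(tr2$discarded$reason, "outlying")

  # random instances against the brute-force oracle; where the first
  # pass discards nothing, a second pass must also discard nothing
  for (s in 1:25) {
    set.seed(s)
    n <- 40
    w <- c(1, 0, rbinom(n - 2, 1, 0.5))
    e <- plogis(rnorm(n, 0.5 * w, 1))
    ps_s <- mk_ps(e, w)
    tr_s <- trim_overlap(ps_s)
    expect_equal(tr_s$keep, oracle_trim(e, w))
    if (all(tr_s$keep)) {
      expect_true(all(trim_overlap(ps_s)$keep))
    }
  }
})

test_that("caliper matching is greedy, seeded, and deterministic", {
  mk_ps <- function(scores, exposed) {
    structure(list(scores = scores, exposed = exposed,
                   date = seq(as.Date("2015-01-01"), by = "day",
                              length.out = length(scores))),
              class = "wc_propensity")
  }
  # the only admissible pair is taken
  ps <- mk_ps(c(0.50, 0.52), c(1, 0))
  m <- match_caliper(ps, caliper = 0.5, seed = 1)
  expect_equal(nrow(m$pairs), 1)
  # distance beyond the caliper: zero pairs, both days logged unmatched
  m2 <- match_caliper(ps, caliper = 0.01, seed = 1)
  expect_equal(nrow(m2$pairs), 0)
  expect_setequal(m2$discarded$date, ps$date)
  expect_true(all(m2$discarded$reason == "unmatched"))
  expect_error(match_caliper(ps, caliper = 0), "positive")

  # equidistant controls are broken by the seed, reproducibly
  ps3 <- mk_ps(c(0.5, 0.45, 0.55), c(1, 0, 0))
  picks <- sapply(1:40, function(s) {
    as.character(match_caliper(ps3, caliper = 1, seed = s)$pairs$control_date)
  })
  expect_equal(length(unique(picks)), 2)
  expect_identical(match_caliper(ps3, caliper = 1, seed = 7)$pairs,
                   match_caliper(ps3, caliper = 1, seed = 7)$pairs)

  # random instances agree with the naive greedy re-implementation
  for (s in 1:25) {
    set.seed(100 + s)
    w <- c(rep(1, 5), rep(0, 7))
    e <- runif(12, 0.2, 0.8)
    ps_s <- mk_ps(e, w)
    cal <- 0.3
    got <- match_caliper(ps_s, caliper = cal, seed = s)
    want <- oracle_greedy_match(e, w, ps_s$date, cal, seed = s)
    if (is.null(want)) {
      expect_equal(nrow(got$pairs), 0)
    } else {
      expect_equal(got$pairs$exposed_date, want$exposed_date)
      expect_equal(got$pairs$control_date, want$control_date)
    }
  }
})

test_that("standardized mean differences follow the pooled-SD formula", {
  # identical covariate distributions in both arms: SMD exactly 0
  d0 <- data.frame(date = seq(as.Date("2015-01-01"), by = "day",
                              length.out = 300),
                   exposed = rep(c(1L, 0L), each = 150),
                   X = rep(rep(c(1, 2, 3), 50), 2))
  bal0 <- balance_smd(d0, "X")
  expect_equal(bal0$smd_before, 0, tolerance = 1e-12)

  # arithmetic case with known pooled SD
  d1 <- data.frame(date = seq(as.Date("2015-01-01"), by = "day",
                              length.out = 8),
                   exposed = rep(c(1L, 0L), each = 4),
                   B = c(1, 1, 1, 0, 0, 0, 0, 1))
  bal1 <- balance_smd(d1, "B")
  expect_equal(bal1$smd_before, oracle_smd(d1$B, d1$exposed))
  expect_equal(bal1$smd_before, 0.5 / 0.5)

  # zero pooled SD flags non-finite instead of crashing
  d1$Z <- 1
  expect_true(is.nan(balance_smd(d1, "Z")$smd_before))

  # random instances against direct formula evaluation, before and after
  for (s in 1:25) {
    ds <- make_ps_design(60, seed = 400 + s)
    ps <- estimate_propensity(ds, ~X)
    m <- match_caliper(ps, caliper = 1, seed = s)
    bal <- balance_smd(ds, "X", matched = m)
    expect_equal(bal$smd_before, oracle_smd(ds$X, ds$exposed))
    if (nrow(m$pairs)) {
      expect_equal(bal$smd_after,
                   oracle_smd(ds$X, ds$exposed,
                              match(m$pairs$exposed_date, ds$date),
                              match(m$pairs$control_date, ds$date)))
    }
  }
})

test_that("matching improves balance on a confounded design", {
  wins <- 0
  for (s in 1:20) {
    d <- make_ps_design(1000, seed = 500 + s, beta = 0.8)
    ps <- estimate_propensity(d, ~X)
    tr <- trim_overlap(ps)
    m <- match_caliper(ps, keep = tr$keep, seed = s)
    bal <- balance_smd(d, "X", matched = m)
    if (abs(bal$smd_after) <= abs(bal$smd_before)) wins <- wins + 1
  }
  expect_gte(wins, 11)
})

test_that("the design stage never sees an outcome column", {
  synth <- generate_synthetic(synthetic_config(n_days = 120, seed = 3))
  spec <- boston_experiments()$MildHI
  arms <- assign_arms(synth$study, spec)
  design <- design_table(synth$study, arms)
  expect_length(intersect(c("violent", "aggravated_assault", "larceny"),
                          names(design)), 0)
})
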