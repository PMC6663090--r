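mk_imp <- function(Y1, Y0, dates = NULL, arm = NULL) {
  n <- nrow(Y1)
  structure(list(Y1 = Y1, Y0 = Y0,
                 dates = dates %||% (as.Date("2015-01-01") + seq_len(n) - 1),
                 arm = arm %||% rep("exposed", n),
                 y_obs = Y1[, 1], outcome = "violent", R = ncol(Y1),
                 seed = 1L),
            class = "wc_imputations")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("the two-day worked example gives an AEE of exactly 2", {
  # exposed day: observed Y(1)=5, imputed Y(0)=3
  # control day: imputed Y(1)=4, observed Y(0)=2
  imp <- mk_imp(Y1 = matrix(c(5, 4), 2, 1), Y0 = matrix(c(3, 2), 2, 1),
                arm = c("exposed", "control"))
  aee <- compute_aee(imp)
  expect_identical(aee$estimate, 2)
  expect_equal(aee$N, 2)
})

test_that("constant draws collapse the posterior summary", {
  imp <- mk_imp(Y1 = matrix(5, 3, 200), Y0 = matrix(3, 3, 200))
  aee <- compute_aee(imp)
  expect_equal(aee$estimate, 2)
  expect_equal(aee$interval, c(2, 2))
})

test_that("replication-level AEE equals the potential-outcome column means", {
  set.seed(10)
  Y1 <- matrix(rpois(50 * 40, 6), 50, 40)
  Y0 <- matrix(rpois(50 * 40, 5), 50, 40)
  aee <- compute_aee(mk_imp(Y1, Y0))
  # finite-population identity, via an independent elementwise route
  expect_equal(aee$draws, colMeans(Y1 - Y0))
  expect_lte(aee$interval[1], aee$estimate)
  expect_gte(aee$estimate, aee$interval[1])
  expect_lte(aee$estimate, aee$interval[2])
})

test_that("a missing potential outcome is reported by day and replication", {
  Y1 <- matrix(5, 2, 3)
  Y0 <- matrix(3, 2, 3)
  Y0[2, 2] <- NA
  expect_error(compute_aee(mk_imp(Y1, Y0)), "2015-01-02.*replication 2")
})

test_that("imputation pairs draw r with replication r and stays in-arm", {
  set.seed(44)
  n <- 60
  d <- data.frame(date = as.Date("2015-01-01") + 0:(n - 1),
                  arm = rep(c("exposed", "control"), n / 2),
                  B = rbinom(n, 1, 0.5),
                  violent = rnbinom(n, size = 8, mu = 12))
  sp <- nb_model_spec("violent", ~ B, mcmc = fast_mcmc(2))
  fe <- fit_outcome_nb(d[d$arm == "exposed", ], sp)
  fc <- fit_outcome_nb(d[d$arm == "control", ], sp)
  imp <- impute_potential_outcomes(d, fe, fc, R = 200, seed = 9)
  expect_equal(dim(imp$Y1), c(n, 200))
  # observed-data anchoring: observed entries identical across replications
  is_exp <- d$arm == "exposed"
  expect_true(all(imp$Y1[is_exp, ] == d$violent[is_exp]))
  expect_true(all(imp$Y0[!is_exp, ] == d$violent[!is_exp]))
  expect_true(all(imp$Y1 >= 0) && all(imp$Y0 >= 0))
  expect_true(all(imp$Y1 == round(imp$Y1)))
  # determinism: same seed, bit-identical imputations
  imp2 <- impute_potential_outcomes(d, fe, fc, R = 200, seed = 9)
  expect_identical(imp$Y1, imp2$Y1)
  expect_identical(imp$Y0, imp2$Y0)
  # R above the retained draw count is an error
  expect_error(impute_potential_outcomes(d, fe, fc, R = 10001, seed = 1),
               "exceeds")
})

test_that("degenerate concentrated posteriors give a near-zero AEE", {
  n <- 200
  d <- data.frame(date = as.Date("2015-01-01") + 0:(n - 1),
                  arm = rep(c("exposed", "control"), n / 2),
                  violent = rep(7L, n))
  mk_fit <- function() {
    draws <- cbind("(Intercept)" = rep(log(7), 500), phi = rep(1e7, 500))
    structure(list(draws = draws, formula = ~1, outcome = "violent",
                   standardize = FALSE, scaling = NULL),
              class = "wc_nbfit")
  }
  imp <- impute_potential_outcomes(d, mk_fit(), mk_fit(), R = 500, seed = 3)
  aee <- compute_aee(imp)
  expect_lt(abs(aee$estimate), 0.1)
  expect_lt(max(abs(aee$draws)), 1.5)
})

test_that("absolute change scales the point estimate linearly", {
  expect_equal(absolute_change(1.88, 30)$change, 56.4)
  expect_equal(absolute_change(0, 365)$change, 0)
  a10 <- absolute_change(1.88, 10)$change
  expect_equal(absolute_change(1.88, 20)$change, 2 * a10)
  imp <- mk_imp(Y1 = matrix(5, 3, 100), Y0 = matrix(3, 3, 100))
  ac <- absolute_change(compute_aee(imp), 30)
  expect_equal(ac$change, 60)
  expect_equal(ac$interval, c(60, 60))
  expect_error(absolute_change(1.88, 0), "n_days")
})

test_that("spatial summaries are per-area daily means with zero fill", {
  days <- as.Date("2016-01-01") + 0:1
  crimes <- data.frame(
    date = rep(days, c(2, 4)),
    zip_area = c("02101", "02101", "02101", "02101", "02101", "02101"))
  out <- spatial_summary(crimes, list(all = days))
  expect_equal(out$mean_daily, 3.0)

  # an area with no incidents still appears, with mean zero
  out2 <- spatial_summary(crimes, list(all = days),
                          areas = c("02101", "02199"))
  expect_equal(out2$mean_daily[out2$zip_area == "02199"], 0)

  expect_error(spatial_summary(crimes, list(none = as.Date(character(0)))),
               "empty day set")

  # random instance against a brute-force tally/mean
  set.seed(19)
  days30 <- as.Date("2016-03-01") + 0:29
  n <- 600
  cr <- data.frame(date = sample(days30, n, replace = TRUE),
                   zip_area = sample(sprintf("021%02d", 1:5), n,
                                     replace = TRUE))
  sets <- list(a = days30[1:10], b = days30[11:30])
  out3 <- spatial_summary(cr, sets)
  for (nm in names(sets)) {
    for (z in sprintf("021%02d", 1:5)) {
      want <- sum(cr$date %in% sets[[nm]] & cr$zip_area == z) /
        length(sets[[nm]])
      expect_equal(out3$mean_daily[out3$set == nm & out3$zip_area == z],
                   want)
    }
  }
  # weighted area means reproduce the citywide mean
  w <- out3[out3$set == "a", ]
  expect_equal(sum(w$mean_daily), sum(cr$date %in% sets$a) / 10)
})
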