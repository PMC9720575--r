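# Marginal effects, chi-square critical values, transferability test.

test_that("marginal effects match brute-force counterfactual differencing", {
  truth <- make_mnl_truth()
  d <- make_mnl_dataset(50, seed = 61)
  fit <- fit_mixed_logit(d, as_ml_spec(truth))
  me <- marginal_effects(fit)
  # independent oracle: naive probability differencing per observation
  zero_noise <- matrix(numeric(0), 50, 0)
  truth_hat <- truth
  for (a in names(truth_hat$fixed)) {
    for (v in names(truth_hat$fixed[[a]])) {
      truth_hat$fixed[[a]][[v]] <- fit$theta[[paste0(a, ":", v)]]
    }
  }
  truth_hat$constants <- c(
    SI = fit$theta[["const:SI"]], MIN = fit$theta[["const:MIN"]]
  )
  for (v in me$variable) {
    d1 <- d0 <- d
    d1[[v]] <- 1
    d0[[v]] <- 0
    util <- function(dd) crashmixl:::systematic_utilities(
      truth_hat, dd, realize_coefficients(truth_hat, dd, zero_noise)
    )
    eff <- colMeans(oracle_probs(util(d1))) - colMeans(oracle_probs(util(d0)))
    row <- me[me$variable == v, ]
    expect_equal(
      c(row$me_SI, row$me_MIN, row$me_NI), unname(eff), tolerance = 1e-12
    )
  }
  # rows sum to zero before any rounding
  expect_true(all(abs(me$me_SI + me$me_MIN + me$me_NI) < 1e-10))
})

test_that("marginal effects reject non-binary variables by name", {
  d <- make_mnl_dataset(40, seed = 62)
  fit <- fit_mixed_logit(d, as_ml_spec(make_mnl_truth()))
  d_bad <- dplyr::mutate(d, rollover = rollover + 0.5)
  expect_error(marginal_effects(fit, data = d_bad), "rollover")
})

test_that("mean-shifter handling in marginal effects is switchable", {
  truth <- make_hmv_truth()
  d <- make_hmv_dataset(300, seed = 63)
  spec <- as_ml_spec(truth, n_draws = 60)
  fit <- fit_mixed_logit(d, spec, compute_se = FALSE)
  me_default <- marginal_effects(fit)
  me_grand <- suppressMessages(
    marginal_effects(fit, include_mean_shifters = FALSE)
  )
  expect_true(all(abs(me_default$me_SI + me_default$me_MIN + me_default$me_NI) < 1e-10))
  expect_true(all(abs(me_grand$me_SI + me_grand$me_MIN + me_grand$me_NI) < 1e-10))
  # the two conventions differ when delta is non-zero
  expect_false(isTRUE(all.equal(me_default$me_SI, me_grand$me_SI)))
})

test_that("chi-square quantiles: closed forms and the printed critical value", {
  expect_equal(chi2_quantile(2, 0.5), 2 * log(2), tolerance = 1e-10)
  expect_equal(round(chi2_quantile(15, 0.9999), 2), 44.26)
  expect_equal(sqrt(chi2_quantile(1, 0.95)), qnorm(0.975), tolerance = 1e-10)
  expect_error(chi2_quantile(0, 0.5), "df")
  expect_error(chi2_quantile(2, 1), "0, 1")
})

test_that("transferability statistic, nesting and symmetry behave", {
  # identical pooled and separate likelihood sums -> zero statistic
  res0 <- lr_transferability(-500, -300, -200, df = 4)
  expect_equal(res0$lr_statistic, 0)
  expect_false(res0$separate_models_supported)

  res <- lr_transferability(-8473.43, -4480.001, -3935.43,
                            df = 15, confidence = 0.9999)
  expect_equal(res$critical_value, 44.26, tolerance = 0.005 / 44.26)
  expect_equal(res$lr_statistic,
               -2 * (-8473.43 - (-4480.001) - (-3935.43)))
  expect_true(res$separate_models_supported) # 116 > 44.26
  # symmetric in the group log-likelihoods
  res_swap <- lr_transferability(-8473.43, -3935.43, -4480.001,
                                 df = 15, confidence = 0.9999)
  expect_equal(res$lr_statistic, res_swap$lr_statistic)

  expect_warning(lr_transferability(-100, -60, -60, df = 2), "Negative")
  expect_error(lr_transferability(-10, -5, -4, df = 0), "df")
  expect_error(
    lr_transferability(-10, -5, -4, df = 2, confidence = 1.2), "0, 1"
  )
})

test_that("transferability from fitted objects derives df from parameters", {
  truth <- make_mnl_truth()
  spec <- as_ml_spec(truth)
  d_all <- make_mnl_dataset(900, seed = 64)
  grp <- rep(c("a", "b"), length.out = 900)
  f_all <- fit_mixed_logit(d_all, spec, compute_se = FALSE)
  f_a <- fit_mixed_logit(d_all[grp == "a", ], spec, compute_se = FALSE)
  f_b <- fit_mixed_logit(d_all[grp == "b", ], spec, compute_se = FALSE)
  res <- lr_transferability(f_all, f_a, f_b, confidence = 0.95)
  expect_equal(res$df, length(f_all$theta))
  expect_gte(res$lr_statistic, -1e-6) # pooled nested in the pair
})

test_that("separate-model support rises with the between-group parameter gap", {
  spec <- ml_spec(
    fixed = list(SI = "rollover", MIN = "fatigue"),
    constants = c("SI", "MIN")
  )
  prevs <- c(rollover = 0.2, fatigue = 0.15)
  support_rate <- function(gap) {
    hits <- vapply(1:20, function(s) {
      tr_a <- true_params(
        constants = c(SI = -1, MIN = -0.5),
        fixed = list(SI = c(rollover = 1.0), MIN = c(fatigue = 0.8))
      )
      tr_b <- tr_a
      tr_b$fixed$SI[["rollover"]] <- 1.0 + gap
      tr_b$constants[["SI"]] <- -1 + gap / 2
      d_a <- simulate_outcomes(generate_design(600, prevs, seed = 7000 + s),
                               tr_a, seed = 7100 + s)
      d_b <- simulate_outcomes(generate_design(600, prevs, seed = 7200 + s),
                               tr_b, seed = 7300 + s)
      d_all <- dplyr::bind_rows(d_a, d_b)
      f_all <- fit_mixed_logit(d_all, spec, compute_se = FALSE)
      f_a <- fit_mixed_logit(d_a, spec, compute_se = FALSE)
      f_b <- fit_mixed_logit(d_b, spec, compute_se = FALSE)
      lr_transferability(f_all, f_a, f_b,
                         confidence = 0.95)$separate_models_supported
    }, logical(1))
    mean(hits)
  }
  rates <- vapply(c(0, 0.8, 2.0), support_rate, numeric(1))
  expect_lte(rates[1], rates[2] + 0.05)
  expect_lte(rates[2], rates[3] + 0.05)
  expect_gt(rates[3], rates[1])
  expect_gt(rates[3], 0.8) # large gaps are detected nearly always
})
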