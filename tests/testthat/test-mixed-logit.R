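# Core estimator: probabilities, simulated likelihood, fit statistics.

test_that("choice probabilities: symmetry, closed form, direct-formula match", {
  expect_equal(choice_probabilities(c(0, 0, 0)), rep(1 / 3, 3))
  expect_equal(choice_probabilities(c(log(2), 0, 0)), c(0.5, 0.25, 0.25))
  set.seed(17)
  V <- matrix(rnorm(300), 100, 3)
  expect_equal(choice_probabilities(V), oracle_probs(V), tolerance = 1e-12)
  expect_true(all(abs(rowSums(choice_probabilities(V)) - 1) < 1e-12))
  expect_error(choice_probabilities(c(NaN, 0, 0)), "finite")
})

test_that("probabilities are invariant to a common utility shift", {
  set.seed(18)
  V <- matrix(rnorm(60), 20, 3)
  expect_equal(choice_probabilities(V), choice_probabilities(V + 5),
               tolerance = 1e-12)
})

test_that("simulated log-likelihood is -N log 3 at all-zero parameters", {
  d <- make_hmv_dataset(150, seed = 23)
  spec <- as_ml_spec(make_hmv_truth(), n_draws = 60)
  theta <- pack_parameters(spec)
  theta["sigma:rural"] <- 0
  expect_equal(simulated_loglik(theta, d, spec), -150 * log(3))
})

test_that("sigma = 0 simulated likelihood equals the plain-MNL oracle", {
  truth <- make_hmv_truth()
  truth$random$rural$sd <- 0
  d <- make_hmv_dataset(200, seed = 24)
  spec <- as_ml_spec(make_hmv_truth(), n_draws = 40)
  theta <- truth_vector(truth, spec)
  expect_equal(theta[["sigma:rural"]], 0)
  expect_equal(
    simulated_loglik(theta, d, spec),
    oracle_mnl_loglik(d, truth),
    tolerance = 1e-10
  )
})

test_that("likelihood is invariant to a constant added to every utility", {
  # one always-on indicator per alternative with a common coefficient is a
  # pure location shift of the utility system
  truth <- make_mnl_truth()
  d <- make_mnl_dataset(120, seed = 25)
  d$one_si <- 1
  d$one_min <- 1
  d$one_ni <- 1
  spec <- ml_spec(
    fixed = list(
      SI = c(names(truth$fixed$SI), "one_si"),
      MIN = c(names(truth$fixed$MIN), "one_min"),
      NI = c(names(truth$fixed$NI), "one_ni")
    ),
    constants = c("SI", "MIN")
  )
  base <- truth_vector(truth, as_ml_spec(truth))
  th0 <- pack_parameters(spec, base)
  th_shift <- th0
  th_shift[c("SI:one_si", "MIN:one_min", "NI:one_ni")] <- 3.7
  expect_equal(
    simulated_loglik(th0, d, spec),
    simulated_loglik(th_shift, d, spec),
    tolerance = 1e-10
  )
})

test_that("analytic score matches central finite differences", {
  d <- make_hmv_dataset(80, seed = 26)
  spec <- as_ml_spec(make_hmv_truth(), n_draws = 30)
  md <- crashmixl:::prepare_model_data(d, spec)
  cube <- halton_cube(80, 30, 1, 10)
  theta <- truth_vector(make_hmv_truth(), spec) + 0.05
  g <- crashmixl:::mixl_eval(theta, md, cube, want_scores = TRUE)$gradient
  fd <- vapply(seq_along(theta), function(i) {
    h <- 1e-6
    tp <- tm <- theta
    tp[i] <- tp[i] + h
    tm[i] <- tm[i] - h
    (crashmixl:::mixl_eval(tp, md, cube)$ll -
       crashmixl:::mixl_eval(tm, md, cube)$ll) / (2 * h)
  }, numeric(1))
  expect_equal(g, fd, tolerance = 1e-6)
})

test_that("doubling the draw count changes the likelihood by less each time", {
  truth <- make_hmv_truth()
  d <- make_hmv_dataset(200, seed = 27)
  ll_at <- function(draws) {
    spec <- as_ml_spec(truth, n_draws = draws)
    simulated_loglik(truth_vector(truth, spec), d, spec)
  }
  ll <- vapply(c(125, 250, 500, 1000), ll_at, numeric(1))
  deltas <- abs(diff(ll))
  expect_true(all(diff(deltas) < 0))
})

test_that("null log-likelihood conventions reproduce printed values", {
  expect_equal(null_loglik(6943), -7627.665, tolerance = 5e-4 / 7627)
  expect_equal(null_loglik(7206), -7916.60, tolerance = 5e-3 / 7916)
  expect_equal(null_loglik(1), -log(3), tolerance = 1e-4)
  expect_equal(
    null_loglik(100, "constants_only", shares = c(0.2, 0.3, 0.5)),
    100 * (0.2 * log(0.2) + 0.3 * log(0.3) + 0.5 * log(0.5))
  )
  # zero empirical share contributes nothing, with a notice
  expect_message(
    val <- null_loglik(10, "constants_only", shares = c(0.5, 0.5, 0)),
    "Zero"
  )
  expect_equal(val, 10 * log(0.5))
  expect_error(null_loglik(10, shares = c(1, 1, 1)), "constants_only")
})

test_that("McFadden pseudo R-squared matches the printed model summaries", {
  expect_equal(round(pseudo_r2(-4480.001, -7627.665), 3), 0.413)
  expect_equal(round(pseudo_r2(-3935.43, -7916.60), 3), 0.503)
  expect_equal(pseudo_r2(-100, -100), 0)
  expect_error(pseudo_r2(-10, 0), "upper|nonzero|\\[")
})

test_that("sign shares of a normal coefficient reproduce reported percents", {
  expect_equal(share_sign(-1.010, 2.210, "positive")$share_pct_rounded, 32.4)
  expect_equal(share_sign(-1.953, 1.868, "negative")$share_pct_rounded, 85.2)
  expect_equal(share_sign(0, 5, "positive")$share_pct, 50)
  # complement identity
  m <- rnorm(5)
  s <- abs(rnorm(5)) + 0.1
  expect_equal(
    share_sign(m, s, "positive")$share_pct + share_sign(m, s, "negative")$share_pct,
    rep(100, 5)
  )
  expect_error(share_sign(1, 0, "positive"), "positive")
})

test_that("parameter packing round-trips and reports sigma positively", {
  spec <- as_ml_spec(make_hmv_truth())
  vals <- c("mean:rural" = -0.8, "sigma:rural" = -1.6, "const:NI" = 1.2)
  theta <- pack_parameters(spec, vals)
  expect_equal(theta[["sigma:rural"]], -1.6)
  un <- unpack_parameters(spec, theta)
  expect_equal(un$value[un$name == "sigma:rural"], 1.6) # positive scale
  expect_equal(un$value[un$name == "mean:rural"], -0.8)
  expect_error(pack_parameters(spec, c(bogus = 1)), "bogus")
  expect_error(unpack_parameters(spec, 1:3), "length")
})

test_that("constants-only fit attains the analytic multinomial maximum", {
  d <- make_mnl_dataset(600, seed = 28)
  spec <- ml_spec(constants = c("SI", "MIN"))
  fit <- fit_mixed_logit(d, spec)
  counts <- as.numeric(table(d$severity))
  ll_analytic <- sum(counts * log(counts / 600))
  expect_equal(fit$ll, ll_analytic, tolerance = 1e-6 / abs(ll_analytic))
  expect_equal(fit$ll_zero_constants_only, ll_analytic)
  expect_gte(fit$ll, fit$ll_zero_equal_shares) # nesting
  expect_true(fit$pseudo_r2 >= 0 && fit$pseudo_r2 < 1)
})

test_that("plain-MNL fit agrees with the nnet::multinom reference", {
  skip_if_not_installed("nnet")
  d <- make_mnl_dataset(1500, seed = 29)
  # generic specification: every covariate in both non-reference utilities
  vars <- names(mnl_prevalences)
  spec <- ml_spec(
    fixed = list(SI = vars, MIN = vars),
    constants = c("SI", "MIN")
  )
  fit <- fit_mixed_logit(d, spec)
  ref <- nnet::multinom(
    severity ~ rollover + daylight + fatigue + rear_end,
    data = dplyr::mutate(d, severity = stats::relevel(factor(severity), "NI")),
    trace = FALSE, reltol = 1e-12
  )
  expect_equal(fit$ll, as.numeric(stats::logLik(ref)), tolerance = 1e-6)
  co <- summary(ref)$coefficients
  expect_equal(
    fit$theta[["SI:rollover"]], co["SI", "rollover"], tolerance = 1e-3
  )
  expect_equal(
    fit$theta[["const:MIN"]], co["MIN", "(Intercept)"], tolerance = 1e-3
  )
})

test_that("MNL estimates cover the truth at the nominal rate", {
  truth <- make_mnl_truth()
  spec <- as_ml_spec(truth)
  tv <- truth_vector(truth, spec)
  covered <- integer(0)
  for (rep in 1:50) {
    d <- make_mnl_dataset(5000, seed = 100 + rep)
    fit <- fit_mixed_logit(d, spec)
    ci_lo <- fit$theta - qnorm(0.975) * fit$estimates$std_error
    ci_hi <- fit$theta + qnorm(0.975) * fit$estimates$std_error
    covered <- c(covered, tv >= ci_lo & tv <= ci_hi)
  }
  expect_gte(mean(covered), 0.90)
})

test_that("adding a truly relevant variable never lowers the optimum", {
  truth <- make_mnl_truth()
  d <- make_mnl_dataset(1000, seed = 30)
  spec_small <- ml_spec(
    fixed = list(SI = c("rollover", "daylight"), MIN = "fatigue"),
    constants = c("SI", "MIN")
  )
  spec_full <- as_ml_spec(truth)
  ll_small <- fit_mixed_logit(d, spec_small)$ll
  ll_full <- fit_mixed_logit(d, spec_full)$ll
  expect_gte(ll_full, ll_small - 1e-8)
})

test_that("a single mixed-logit fit maximises the simulated likelihood", {
  truth <- make_hmv_truth()
  d <- make_hmv_dataset(4000, seed = 55)
  spec <- as_ml_spec(truth, n_draws = 500)
  fit <- fit_mixed_logit(d, spec)
  expect_true(fit$convergence$converged)
  # the simulated likelihood is shallow near its optimum at this scale;
  # require per-observation flatness rather than the strict absolute norm
  expect_lt(fit$convergence$gradient_norm / fit$n_obs, 1e-5)
  expect_equal(fit$n_draws, 500)
  # the optimum dominates the generating parameters under the same draws
  tv <- truth_vector(truth, spec)
  expect_gte(fit$ll, simulated_loglik(tv, d, spec))
  expect_gte(fit$ll, fit$ll_zero)
  # well-identified parameters (constants, fixed coefficients, delta) land
  # within sampling error of the truth; the (mean, sigma) pair of a random
  # coefficient is weakly identified at this n and is checked through the
  # multi-size RMSE study instead
  td <- tidy(fit)
  strong <- td$role %in% c("constant", "fixed", "delta")
  dev <- abs(fit$theta - tv) / td$std.error
  expect_true(all(dev[strong] < 3.5))
  expect_true(all(td$estimate[td$role == "sigma"] >= 0))
  expect_true(all(is.finite(td$std.error)))
})
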