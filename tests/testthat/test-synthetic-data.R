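# Synthetic crash-record generator: designs, realised coefficients,
# simulated outcomes.

test_that("Bernoulli designs honour degenerate and interior prevalences", {
  d <- generate_design(200, c(a = 0, b = 1, c = 0.5), seed = 7)
  expect_true(all(d$a == 0))
  expect_true(all(d$b == 1))
  d2 <- generate_design(10000, c(x = 0.3), seed = 8)
  expect_lt(abs(mean(d2$x) - 0.3), 3 * sqrt(0.3 * 0.7 / 10000))
  expect_error(generate_design(10, c(x = 1.2), seed = 1), "\\[0, 1\\]")
  expect_error(generate_design(10, c(x = 0.5)), "seed")
  expect_identical(d, generate_design(200, c(a = 0, b = 1, c = 0.5), seed = 7))
})

test_that("realised coefficients follow beta + delta.z + sigma*exp(omega.w)*v", {
  tr <- true_params(random = list(rural = list(
    alternative = "SI", mean = -1.010, sd = 2.210,
    delta = c(interstate = -0.5), omega = c(tree = log(2))
  )))
  design <- tibble::tibble(
    rural = 1, interstate = c(0, 0, 1, 0), tree = c(0, 0, 0, 1)
  )
  beta <- realize_coefficients(tr, design, noise = c(0, 1, 0, 1))$beta_rural
  expect_equal(beta[1], -1.010)               # zero-noise centre
  expect_equal(beta[2], -1.010 + 2.210)       # one-sd draw: 1.200
  expect_equal(beta[2], 1.200)
  expect_equal(beta[3], -1.010 - 0.5)         # mean shift
  expect_equal(beta[4], -1.010 + 2.210 * 2)   # exp(log 2) doubles the sd
})

test_that("sigma = 0 degenerates to constant coefficients given z", {
  tr <- true_params(random = list(rural = list(
    alternative = "SI", mean = -0.7, sd = 0, delta = c(interstate = 0.4)
  )))
  design <- tibble::tibble(rural = 1, interstate = rep(c(0, 1), 25))
  beta <- realize_coefficients(tr, design, noise = rnorm(50))$beta_rural
  expect_equal(unique(beta[design$interstate == 0]), -0.7)
  expect_equal(unique(beta[design$interstate == 1]), -0.3)
})

test_that("all-zero truth yields one-third outcome shares", {
  tr <- true_params()
  design <- tibble::tibble(dummy = rep(0L, 30000))
  sim <- simulate_outcomes(design, tr, seed = 21)
  shares <- as.numeric(table(sim$severity)) / 30000
  tol <- 3 * sqrt((1 / 3) * (2 / 3) / 30000)
  expect_true(all(abs(shares - 1 / 3) < tol))
})

test_that("a dominant constant routes almost all outcomes to that class", {
  tr <- true_params(constants = c(NI = 10))
  sim <- simulate_outcomes(tibble::tibble(dummy = rep(0L, 2000)), tr, seed = 3)
  expect_gt(mean(sim$severity == "NI"), 0.99)
})

test_that("fixed-coefficient outcome shares match closed-form logit", {
  tr <- make_mnl_truth()
  design <- generate_design(50000, mnl_prevalences, seed = 31)
  sim <- simulate_outcomes(design, tr, seed = 32)
  # closed-form probabilities via the independent naive-formula oracle
  zero_noise <- matrix(numeric(0), nrow(design), 0)
  V <- crashmixl:::systematic_utilities(
    tr, design, realize_coefficients(tr, design, zero_noise)
  )
  p_expected <- colMeans(oracle_probs(V))
  p_observed <- as.numeric(table(sim$severity)) / nrow(design)
  mc_se <- sqrt(p_expected * (1 - p_expected) / nrow(design))
  expect_true(all(abs(p_observed - p_expected) < 3 * mc_se))
})

test_that("simulation is a deterministic function of (truth, design, seed)", {
  tr <- make_hmv_truth()
  design <- generate_design(500, hmv_prevalences, seed = 12)
  s1 <- simulate_outcomes(design, tr, seed = 13)
  s2 <- simulate_outcomes(design, tr, seed = 13)
  expect_identical(s1$severity, s2$severity)
  expect_identical(attr(s1, "realized_params"), attr(s2, "realized_params"))
  expect_error(simulate_outcomes(design, tr), "seed")

  # outcomes are the argmax of the stored realised utilities
  util <- attr(s1, "realized_utilities")
  expect_identical(
    as.character(s1$severity),
    tr$alternatives[max.col(util, ties.method = "first")]
  )
  # missing covariates are rejected with the variable named
  expect_error(
    simulate_outcomes(design[, c("rollover", "fatigue")], tr, seed = 1),
    "rural"
  )
})

test_that("scenario files round-trip through YAML", {
  sc <- preset_scenario(n = 123, seed = 9)
  path <- withr::local_tempfile(fileext = ".yml")
  write_scenario(sc, path)
  sc2 <- read_scenario(path)
  expect_equal(sc2$n, 123)
  expect_equal(sc2$prevalences, sc$prevalences)
  expect_equal(truth_vector(sc2$truth), truth_vector(sc$truth))
  expect_identical(
    simulate_scenario(sc)$severity,
    simulate_scenario(sc2)$severity
  )
})
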