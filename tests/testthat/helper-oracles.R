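# Independent oracles and shared fixtures.  The oracles deliberately avoid
# the package's own utility/probability code paths: probabilities are
# computed by the plain exp/sum formula with explicit loops.

# Direct multinomial-logit log-likelihood from a truth-style parameter list
# (random coefficients collapsed to their conditional means: sd ignored,
# delta.z respected).  Loops over rows and alternatives on purpose.
oracle_mnl_loglik <- function(data, truth) {
  alts <- truth$alternatives
  ll <- 0
  for (i in seq_len(nrow(data))) {
    v <- setNames(numeric(length(alts)), alts)
    for (a in names(truth$constants)) v[a] <- v[a] + truth$constants[[a]]
    for (a in names(truth$fixed)) {
      for (x in names(truth$fixed[[a]])) {
        v[a] <- v[a] + truth$fixed[[a]][[x]] * data[[x]][i]
      }
    }
    for (vn in names(truth$random)) {
      rt <- truth$random[[vn]]
      b <- rt$mean
      for (z in names(rt$delta)) b <- b + rt$delta[[z]] * data[[z]][i]
      v[rt$alternative] <- v[rt$alternative] + b * data[[vn]][i]
    }
    num <- exp(v[[as.character(data$severity[i])]])
    ll <- ll + log(num / sum(exp(v)))
  }
  ll
}

# Direct per-row choice probabilities from explicit utilities (matrix),
# naive formula.
oracle_probs <- function(V) {
  t(apply(V, 1, function(row) exp(row) / sum(exp(row))))
}

# One-dimensional star discrepancy (brute force over the sorted sample).
star_discrepancy_1d <- function(x) {
  x <- sort(x)
  n <- length(x)
  i <- seq_len(n)
  max(pmax(x - (i - 1) / n, i / n - x))
}

# Small fixed-coefficient truth used across estimator tests.
make_mnl_truth <- function() {
  true_params(
    constants = c(SI = -1.2, MIN = -0.4),
    fixed = list(
      SI = c(rollover = 1.1, daylight = -0.7),
      MIN = c(fatigue = 0.8),
      NI = c(rear_end = -0.5)
    )
  )
}

mnl_prevalences <- c(
  rollover = 0.15, daylight = 0.55, fatigue = 0.1, rear_end = 0.2
)

# Truth with one random coefficient, one mean-shifter, one variance-shifter
# (the structural shape of the severity models under study).
make_hmv_truth <- function() {
  true_params(
    constants = c(NI = 1.2),
    fixed = list(SI = c(rollover = 1.1), MIN = c(fatigue = 0.8)),
    random = list(rural = list(
      alternative = "SI", mean = -0.8, sd = 1.6,
      delta = c(interstate = -0.6), omega = c(tree = 0.5)
    ))
  )
}

hmv_prevalences <- c(
  rollover = 0.15, fatigue = 0.1, rural = 0.45, interstate = 0.25, tree = 0.1
)

make_hmv_dataset <- function(n, seed, truth = make_hmv_truth()) {
  design <- generate_design(n, hmv_prevalences, seed = seed)
  simulate_outcomes(design, truth, seed = seed + 1000L)
}

make_mnl_dataset <- function(n, seed, truth = make_mnl_truth()) {
  design <- generate_design(n, mnl_prevalences, seed = seed)
  simulate_outcomes(design, truth, seed = seed + 1000L)
}
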