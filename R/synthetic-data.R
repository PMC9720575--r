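# Synthetic crash-record generator: Bernoulli indicator designs, random
# coefficients realised per the heterogeneity-in-means-and-variances model,
# outcomes from Gumbel-error utility maximisation, with stored ground truth.

#' Declare ground-truth parameters for the data-generating process
#'
#' Mirrors the structure of [ml_spec()] but carries numeric values: fixed
#' coefficients per alternative, and per random coefficient its mean
#' `beta`, standard deviation `sigma`, mean-shifter loadings `delta` and
#' variance-shifter loadings `omega`.  A record's realised coefficient is
#' `beta + delta . z + sigma * exp(omega . w) * v` with `v` standard normal.
#'
#' @param constants Named numeric vector of alternative constants, e.g.
#'   `c(NI = 2.0)`.
#' @param fixed Named list keyed by alternative; each element a named
#'   numeric vector of fixed coefficients, e.g.
#'   `list(SI = c(rollover = 1.3))`.
#' @param random Named list keyed by variable; each element a list with
#'   `alternative`, `mean`, `sd` (>= 0) and optional named vectors `delta`
#'   (over mean-shifter attributes) and `omega` (over variance-shifter
#'   attributes).
#' @param alternatives,reference As in [ml_spec()].
#' @return An object of class `true_params`.
#' @examples
#' true_params(
#'   constants = c(NI = 2),
#'   fixed = list(SI = c(rollover = 1.3)),
#'   random = list(rural = list(
#'     alternative = "SI", mean = -1.0, sd = 2.2,
#'     delta = c(interstate = -0.6), omega = c(tree = 0.6)
#'   ))
#' )
#' @export
true_params <- function(constants = numeric(), fixed = list(), random = list(),
                        alternatives = c("SI", "MIN", "NI"),
                        reference = "NI") {
  alternatives <- as.character(alternatives)
  if (length(constants) > 0 &&
      (is.null(names(constants)) || !all(names(constants) %in% alternatives))) {
    abort("`constants` must be named by alternative.")
  }
  if (length(fixed) > 0 &&
      (is.null(names(fixed)) || !all(names(fixed) %in% alternatives))) {
    abort("`fixed` must be a named list keyed by alternative.")
  }
  for (v in names(random)) {
    rt <- random[[v]]
    if (!all(c("alternative", "mean", "sd") %in% names(rt))) {
      abort(sprintf(
        "Random term `%s` needs `alternative`, `mean` and `sd`.", v
      ))
    }
    if (rt$sd < 0) {
      abort(sprintf("Random term `%s` has negative sd.", v))
    }
  }
  structure(
    list(
      alternatives = alternatives, reference = reference,
      constants = constants, fixed = fixed, random = random
    ),
    class = "true_params"
  )
}

truth_variables <- function(truth) {
  unique(c(
    unlist(lapply(truth$fixed, names), use.names = FALSE),
    names(truth$random),
    unlist(lapply(truth$random, function(rt) {
      c(names(rt$delta), names(rt$omega))
    }), use.names = FALSE)
  ))
}

#' Derive the matching estimation specification from ground truth
#'
#' @param truth A [true_params()] object.
#' @param ... Passed to [ml_spec()] (e.g. `n_draws`).
#' @return An [ml_spec()] whose terms mirror the data-generating process.
#' @export
as_ml_spec <- function(truth, ...) {
  stopifnot(inherits(truth, "true_params"))
  ml_spec(
    fixed = lapply(truth$fixed, names),
    random = lapply(truth$random, function(rt) {
      rand_term(
        rt$alternative,
        mean_shifters = names(rt$delta) %||% character(),
        sd_shifters = names(rt$omega) %||% character()
      )
    }),
    alternatives = truth$alternatives,
    reference = truth$reference,
    constants = names(truth$constants) %||% character(),
    ...
  )
}

#' Pack ground truth into the estimation parameter vector
#'
#' @param truth A [true_params()] object.
#' @param spec The matching [ml_spec()] (defaults to [as_ml_spec()]).
#' @return Named numeric vector in the spec's layout order.
#' @export
truth_vector <- function(truth, spec = as_ml_spec(truth)) {
  vals <- c(
    setNames(as.numeric(truth$constants),
             paste0("const:", names(truth$constants))),
    unlist(lapply(names(truth$fixed), function(a) {
      setNames(as.numeric(truth$fixed[[a]]),
               paste0(a, ":", names(truth$fixed[[a]])))
    })),
    unlist(lapply(names(truth$random), function(v) {
      rt <- truth$random[[v]]
      c(
        setNames(rt$mean, paste0("mean:", v)),
        setNames(as.numeric(rt$delta %||% numeric()),
                 paste0("delta:", v, ":", names(rt$delta))),
        setNames(rt$sd, paste0("sigma:", v)),
        setNames(as.numeric(rt$omega %||% numeric()),
                 paste0("omega:", v, ":", names(rt$omega)))
      )
    }))
  )
  pack_parameters(spec, vals)
}

#' Generate a Bernoulli indicator design table
#'
#' Emulates the indicator covariates of a crash-record extract: independent
#' 0/1 columns with configurable prevalence.
#'
#' @param n Number of records.
#' @param prevalences Named numeric vector of P(indicator = 1), each in
#'   \[0, 1\].
#' @param seed Integer seed (required; generation is reproducible by
#'   contract).
#' @return Tibble of `n` rows with one integer column per indicator.
#' @examples
#' generate_design(5, c(rural = 0.4, rollover = 0.1), seed = 1)
#' @export
generate_design <- function(n, prevalences, seed) {
  n <- check_count(n, "n")
  if (missing(seed) || is.null(seed)) {
    abort("`seed` is required: design generation must be reproducible.")
  }
  if (length(prevalences) == 0 || is.null(names(prevalences)) ||
      any(!nzchar(names(prevalences)))) {
    abort("`prevalences` must be a named numeric vector.")
  }
  if (any(prevalences < 0 | prevalences > 1 | is.na(prevalences))) {
    abort("Every prevalence must lie in [0, 1].")
  }
  withr::with_seed(seed, {
    cols <- lapply(prevalences, function(p) rbinom(n, 1L, p))
    tibble::as_tibble(cols)
  })
}

#' Realise per-observation coefficients from ground truth
#'
#' Applies the heterogeneity-in-means-and-variances construction to every
#' design row: for random coefficient k,
#' `beta_k(n) = beta + delta . z_n + sigma * exp(omega . w_n) * v_nk`;
#' fixed coefficients pass through unchanged.
#'
#' @param truth A [true_params()] object.
#' @param design Data frame of covariates covering every attribute the
#'   truth references.
#' @param noise Numeric matrix `nrow(design) x n_random` of standard-normal
#'   disturbances, columns in `names(truth$random)` order (a vector is
#'   accepted for a single random term).
#' @return Tibble with one column per random coefficient (named
#'   `beta_<variable>`), one row per design row.
#' @examples
#' tr <- true_params(random = list(
#'   rural = list(alternative = "SI", mean = -1.010, sd = 2.210)
#' ))
#' realize_coefficients(tr, tibble::tibble(rural = 1), noise = 1)
#' @export
realize_coefficients <- function(truth, design, noise) {
  stopifnot(inherits(truth, "true_params"))
  vars <- names(truth$random) %||% character()
  n <- nrow(design)
  noise <- as.matrix(noise)
  if (nrow(noise) != n || ncol(noise) != length(vars)) {
    abort(sprintf(
      "`noise` must be %d x %d (one standard-normal column per random term).",
      n, length(vars)
    ))
  }
  out <- lapply(seq_along(vars), function(k) {
    rt <- truth$random[[vars[k]]]
    mu <- rep(rt$mean, n)
    for (z in names(rt$delta)) mu <- mu + rt$delta[[z]] * design[[z]]
    logscale <- rep(0, n)
    for (w in names(rt$omega)) logscale <- logscale + rt$omega[[w]] * design[[w]]
    mu + rt$sd * exp(logscale) * noise[, k]
  })
  nm <- if (length(vars)) paste0("beta_", vars) else character(0)
  tibble::as_tibble(setNames(out, nm), .rows = n)
}

# Systematic utilities (no Gumbel error) given per-observation realised
# random coefficients; used by the simulator and by tests.
systematic_utilities <- function(truth, design, realized) {
  n <- nrow(design)
  alts <- truth$alternatives
  v_mat <- matrix(0, n, length(alts), dimnames = list(NULL, alts))
  for (a in names(truth$constants)) {
    v_mat[, a] <- v_mat[, a] + truth$constants[[a]]
  }
  for (a in names(truth$fixed)) {
    for (x in names(truth$fixed[[a]])) {
      v_mat[, a] <- v_mat[, a] + truth$fixed[[a]][[x]] * design[[x]]
    }
  }
  for (v in names(truth$random)) {
    a <- truth$random[[v]]$alternative
    v_mat[, a] <- v_mat[, a] + realized[[paste0("beta_", v)]] * design[[v]]
  }
  v_mat
}

#' Simulate severity outcomes from ground truth
#'
#' For each design row, draws the random coefficients, adds independent
#' standard Gumbel (extreme value type I) errors to the three systematic
#' utilities, and records the utility-maximising alternative as the
#' outcome.  Gumbel errors are drawn by inverse CDF, `-log(-log(u))`.
#'
#' @param design Covariate tibble from [generate_design()] (or any data
#'   frame covering the truth's variables).
#' @param truth A [true_params()] object.
#' @param seed Integer seed (required).
#' @param kabco Also emit a `severity_kabco` column consistent with the
#'   class (SI -> K or A, MIN -> B or C, NI -> O), so the schema loading
#'   path can be exercised end to end.
#' @return Tibble: the design columns plus `severity` (factor SI/MIN/NI).
#'   Attributes: `"truth"`, `"seed"`, `"realized_params"` (tibble of
#'   per-observation random-coefficient draws) and `"realized_utilities"`
#'   (matrix of utilities including the Gumbel errors).
#' @examples
#' tr <- true_params(constants = c(NI = 1),
#'                   fixed = list(SI = c(rollover = 1.3)))
#' d <- generate_design(100, c(rollover = 0.2), seed = 2)
#' table(simulate_outcomes(d, tr, seed = 3)$severity)
#' @export
simulate_outcomes <- function(design, truth, seed, kabco = FALSE) {
  stopifnot(inherits(truth, "true_params"))
  if (missing(seed) || is.null(seed)) {
    abort("`seed` is required: outcome simulation must be reproducible.")
  }
  missing_vars <- setdiff(truth_variables(truth), names(design))
  if (length(missing_vars) > 0) {
    abort(sprintf(
      "`design` lacks column(s) referenced by the truth: %s.",
      paste(missing_vars, collapse = ", ")
    ))
  }
  n <- nrow(design)
  alts <- truth$alternatives
  withr::with_seed(seed, {
    noise <- matrix(rnorm(n * length(truth$random)), nrow = n,
                    ncol = length(truth$random))
    realized <- realize_coefficients(truth, design, noise)
    v_sys <- systematic_utilities(truth, design, realized)
    gumbel <- -log(-log(matrix(runif(n * length(alts)), n)))
    util <- v_sys + gumbel
    outcome <- alts[max.col(util, ties.method = "first")]
    out <- dplyr::mutate(
      tibble::as_tibble(design),
      severity = factor(outcome, levels = alts)
    )
    if (isTRUE(kabco)) {
      pick <- function(sev, codes) sample(codes, sum(sev), replace = TRUE)
      kab <- character(n)
      kab[outcome == "SI"] <- pick(outcome == "SI", c("K", "A"))
      kab[outcome == "MIN"] <- pick(outcome == "MIN", c("B", "C"))
      kab[outcome == "NI"] <- "O"
      out$severity_kabco <- kab
    }
  })
  attr(out, "truth") <- truth
  attr(out, "seed") <- seed
  attr(out, "realized_params") <- realized
  attr(out, "realized_utilities") <- util
  out
}

#' Preset synthetic-crash scenario
#'
#' A ready-made scenario with the structural shape of a statewide five-year
#' large-truck extract: ~7000 records, indicator covariates with
#' prevalences in the range seen in such tables, one normally distributed
#' random coefficient (rural, defined for severe injury) with one
#' mean-shifter (interstate) and one variance-shifter (tree), and fixed
#' coefficients of realistic magnitude.
#'
#' @param n Number of records.
#' @param seed Scenario seed.
#' @return A list with elements `n`, `prevalences`, `truth`, `seed`,
#'   of class `sim_scenario`.
#' @export
preset_scenario <- function(n = 7000, seed = 20160101) {
  structure(
    list(
      n = n,
      prevalences = c(
        rural = 0.45, rollover = 0.14, fatigue = 0.02, rear_end = 0.20,
        interstate = 0.22, tree = 0.018, daylight = 0.55
      ),
      truth = true_params(
        constants = c(NI = 2.0),
        fixed = list(
          SI = c(rollover = 1.33, daylight = -0.86),
          MIN = c(fatigue = 0.52),
          NI = c(rear_end = -0.71)
        ),
        random = list(rural = list(
          alternative = "SI", mean = -1.01, sd = 2.21,
          delta = c(interstate = -0.57), omega = c(tree = 0.63)
        ))
      ),
      seed = seed
    ),
    class = "sim_scenario"
  )
}

#' Read / write synthetic scenarios as YAML
#'
#' @param scenario A `sim_scenario` list (see [preset_scenario()]).
#' @param path File path.
#' @return `read_scenario()` returns a `sim_scenario`;
#'   `write_scenario()` returns `path` invisibly.
#' @export
write_scenario <- function(scenario, path) {
  stopifnot(inherits(scenario, "sim_scenario"))
  tr <- scenario$truth
  yaml::write_yaml(
    list(
      n = scenario$n,
      seed = scenario$seed,
      prevalences = as.list(scenario$prevalences),
      truth = list(
        alternatives = tr$alternatives,
        reference = tr$reference,
        constants = as.list(tr$constants),
        fixed = lapply(tr$fixed, as.list),
        random = lapply(tr$random, function(rt) {
          list(
            alternative = rt$alternative, mean = rt$mean, sd = rt$sd,
            delta = as.list(rt$delta %||% numeric()),
            omega = as.list(rt$omega %||% numeric())
          )
        })
      )
    ),
    path
  )
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$n) || raw$n < 1) {
    abort("Scenario must declare a positive `n`.")
  }
  if (is.null(raw$seed)) {
    abort("Scenario must declare a `seed`.")
  }
  tr <- raw$truth
  structure(
    list(
      n = as.integer(raw$n),
      prevalences = unlist(raw$prevalences),
      truth = true_params(
        constants = unlist(tr$constants) %||% numeric(),
        fixed = lapply(tr$fixed, unlist),
        random = lapply(tr$random, function(rt) {
          list(
            alternative = rt$alternative, mean = rt$mean, sd = rt$sd,
            delta = unlist(rt$delta), omega = unlist(rt$omega)
          )
        }),
        alternatives = unlist(tr$alternatives) %||% c("SI", "MIN", "NI"),
        reference = tr$reference %||% "NI"
      ),
      seed = as.integer(raw$seed)
    ),
    class = "sim_scenario"
  )
}

#' Run a scenario end-to-end
#'
#' @param scenario A `sim_scenario`.
#' @param kabco Passed to [simulate_outcomes()].
#' @return The simulated record tibble (see [simulate_outcomes()]).
#' @export
simulate_scenario <- function(scenario, kabco = FALSE) {
  stopifnot(inherits(scenario, "sim_scenario"))
  design <- generate_design(scenario$n, scenario$prevalences,
                            seed = scenario$seed)
  simulate_outcomes(design, scenario$truth, seed = scenario$seed + 1L,
                    kabco = kabco)
}
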