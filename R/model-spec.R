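# Declarative model specification for the three-alternative utility system
# and the packed parameter-vector layout derived from it.

#' Declare a random coefficient
#'
#' Describes one random term of the utility system: the alternative whose
#' utility the variable enters, the attributes that shift the coefficient's
#' mean (`delta . z`) and those that scale its standard deviation
#' (`sigma * exp(omega . w)`), and the mixing distribution.
#'
#' @param alternative Alternative the variable is defined for.
#' @param mean_shifters Character vector of z-attribute names (may be empty).
#' @param sd_shifters Character vector of w-attribute names (may be empty).
#' @param distribution Mixing distribution: `"normal"` (default),
#'   `"lognormal"`, `"uniform"` or `"triangular"`.
#' @return A `rand_term` list used inside [ml_spec()].
#' @export
rand_term <- function(alternative, mean_shifters = character(),
                      sd_shifters = character(), distribution = "normal") {
  distribution <- match.arg(distribution,
    c("normal", "lognormal", "uniform", "triangular"))
  structure(
    list(
      alternative = as.character(alternative),
      mean_shifters = as.character(mean_shifters),
      sd_shifters = as.character(sd_shifters),
      distribution = distribution
    ),
    class = "rand_term"
  )
}

#' Specify a random-parameters multinomial logit model
#'
#' Declares the utility system of a three-alternative (by default
#' SI / MIN / NI) crash-severity model.  Every variable is attached to
#' exactly one alternative ("defined for" that severity class) and enters
#' only that utility.  Coefficients are fixed unless the variable appears
#' in `random`, in which case it varies across crashes with mean
#' `beta + delta . z` and standard deviation `sigma * exp(omega . w)`.
#'
#' @param fixed Named list mapping an alternative to the character vector of
#'   indicator variables with fixed coefficients in its utility, e.g.
#'   `list(SI = c("rollover"), MIN = c("fatigue"))`.
#' @param random Named list mapping a variable name to a [rand_term()].
#' @param alternatives Ordered outcome labels; the default three-class
#'   severity scale.
#' @param reference Reference alternative (utility normalised to carry no
#'   constant unless listed in `constants`).
#' @param constants Alternatives whose utility carries an estimated
#'   constant.  Defaults to all non-reference alternatives; any subset of
#'   size `length(alternatives) - 1` or less is identified.
#' @param n_draws Halton draws per observation for the simulated likelihood.
#' @param discard Initial Halton points dropped per dimension.
#' @param scramble Digit-scramble the Halton sequences (seeded from `fit`'s
#'   `seed` argument).
#' @param max_iter,reltol,grad_tol Optimiser controls: iteration cap,
#'   relative log-likelihood convergence tolerance, and the gradient
#'   max-norm threshold reported in the convergence diagnostics.
#' @return An object of class `ml_spec`.
#' @examples
#' ml_spec(
#'   fixed = list(SI = "rollover", MIN = "fatigue"),
#'   random = list(rural = rand_term("SI", mean_shifters = "interstate")),
#'   n_draws = 200
#' )
#' @export
ml_spec <- function(fixed = list(), random = list(),
                    alternatives = c("SI", "MIN", "NI"),
                    reference = "NI",
                    constants = setdiff(alternatives, reference),
                    n_draws = 1000, discard = 10, scramble = FALSE,
                    max_iter = 500, reltol = 1e-10, grad_tol = 1e-4) {
  alternatives <- as.character(alternatives)
  if (anyDuplicated(alternatives) || length(alternatives) < 2) {
    abort("`alternatives` must be at least two distinct labels.")
  }
  if (!reference %in% alternatives) {
    abort("`reference` must be one of `alternatives`.")
  }
  constants <- as.character(constants)
  if (!all(constants %in% alternatives)) {
    abort("`constants` must name alternatives.")
  }
  if (length(constants) >= length(alternatives)) {
    abort("At most `length(alternatives) - 1` constants are identified.")
  }
  if (length(fixed) > 0 &&
      (is.null(names(fixed)) || !all(names(fixed) %in% alternatives))) {
    abort("`fixed` must be a named list keyed by alternative.")
  }
  fixed <- lapply(fixed, as.character)
  if (length(random) > 0) {
    if (is.null(names(random)) || any(!nzchar(names(random)))) {
      abort("`random` must be a named list: variable -> rand_term().")
    }
    ok <- vapply(random, inherits, logical(1), "rand_term")
    if (!all(ok)) {
      abort("Every element of `random` must be built with rand_term().")
    }
    alts <- vapply(random, `[[`, character(1), "alternative")
    if (!all(alts %in% alternatives)) {
      abort("Random terms reference unknown alternatives.")
    }
  }
  # each variable attaches to exactly one alternative
  fixed_pairs <- unlist(lapply(names(fixed), function(a) {
    paste0(a, ":", fixed[[a]])
  }))
  if (anyDuplicated(fixed_pairs)) {
    abort("Duplicated fixed term (same variable and alternative).")
  }
  # a random variable is one term; it may not double as a fixed term
  clash <- intersect(unlist(fixed, use.names = FALSE), names(random))
  if (length(clash) > 0) {
    abort(sprintf(
      "Variable(s) declared both fixed and random: %s.",
      paste(unique(clash), collapse = ", ")
    ))
  }
  spec <- structure(
    list(
      alternatives = alternatives, reference = reference,
      constants = constants, fixed = fixed, random = random,
      n_draws = check_count(n_draws, "n_draws"),
      discard = check_count(discard, "discard", min = 0L),
      scramble = isTRUE(scramble),
      control = list(
        max_iter = check_count(max_iter, "max_iter"),
        reltol = reltol, grad_tol = grad_tol
      )
    ),
    class = "ml_spec"
  )
  spec$layout <- build_layout(spec)
  spec
}

# Parameter layout: one row per packed entry; pack/unpack by position.
build_layout <- function(spec) {
  rows <- list()
  add <- function(role, variable, alternative, shifter = NA_character_) {
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      role = role, variable = variable, alternative = alternative,
      shifter = shifter
    )
  }
  for (a in spec$constants) add("constant", "(constant)", a)
  for (a in names(spec$fixed)) {
    for (v in spec$fixed[[a]]) add("fixed", v, a)
  }
  for (v in names(spec$random)) {
    rt <- spec$random[[v]]
    add("mean", v, rt$alternative)
    for (z in rt$mean_shifters) add("delta", v, rt$alternative, z)
    add("sigma", v, rt$alternative)
    for (w in rt$sd_shifters) add("omega", v, rt$alternative, w)
  }
  layout <- dplyr::bind_rows(rows)
  layout$name <- with(layout, dplyr::case_when(
    role == "constant" ~ paste0("const:", alternative),
    role == "fixed" ~ paste0(alternative, ":", variable),
    role == "mean" ~ paste0("mean:", variable),
    role == "delta" ~ paste0("delta:", variable, ":", shifter),
    role == "sigma" ~ paste0("sigma:", variable),
    role == "omega" ~ paste0("omega:", variable, ":", shifter)
  ))
  layout
}

#' Number of packed parameters of a model specification
#' @param spec An [ml_spec()].
#' @return Integer count.
#' @export
n_parameters <- function(spec) {
  stopifnot(inherits(spec, "ml_spec"))
  nrow(spec$layout)
}

#' Pack named parameter values into the estimation vector
#'
#' @param spec An [ml_spec()].
#' @param values Named numeric vector or list; names must follow the layout
#'   naming (`const:NI`, `SI:rollover`, `mean:rural`, `delta:rural:interstate`,
#'   `sigma:rural`, `omega:rural:tree`).  Missing entries default to 0
#'   (sigma entries to 0.5).
#' @return Named numeric vector in layout order.
#' @export
pack_parameters <- function(spec, values = numeric()) {
  layout <- spec$layout
  theta <- ifelse(layout$role == "sigma", 0.5, 0)
  names(theta) <- layout$name
  values <- unlist(values)
  if (length(values) > 0) {
    unknown <- setdiff(names(values), layout$name)
    if (length(unknown) > 0) {
      abort(sprintf(
        "Unknown parameter name(s): %s.", paste(unknown, collapse = ", ")
      ))
    }
    theta[names(values)] <- values
  }
  theta
}

#' Unpack an estimation vector into a labelled tibble
#'
#' @param spec An [ml_spec()].
#' @param theta Numeric vector in layout order.
#' @return Tibble with columns `name`, `role`, `variable`, `alternative`,
#'   `shifter`, `value`.  `sigma` rows are reported on the positive scale.
#' @export
unpack_parameters <- function(spec, theta) {
  layout <- spec$layout
  if (length(theta) != nrow(layout)) {
    abort(sprintf(
      "`theta` has length %d; the layout expects %d.",
      length(theta), nrow(layout)
    ))
  }
  value <- as.numeric(theta)
  value[layout$role == "sigma"] <- abs(value[layout$role == "sigma"])
  dplyr::bind_cols(
    layout[, c("name", "role", "variable", "alternative", "shifter")],
    tibble::tibble(value = value)
  )
}

spec_variables <- function(spec) {
  unique(c(
    unlist(spec$fixed, use.names = FALSE),
    names(spec$random),
    unlist(lapply(spec$random, function(rt) c(rt$mean_shifters, rt$sd_shifters)))
  ))
}

#' @export
print.ml_spec <- function(x, ...) {
  cat(sprintf(
    "<ml_spec> alternatives: %s (reference %s)\n",
    paste(x$alternatives, collapse = "/"), x$reference
  ))
  cat(sprintf("  constants: %s\n", paste(x$constants, collapse = ", ")))
  for (a in names(x$fixed)) {
    cat(sprintf("  fixed [%s]: %s\n", a, paste(x$fixed[[a]], collapse = ", ")))
  }
  for (v in names(x$random)) {
    rt <- x$random[[v]]
    cat(sprintf(
      "  random [%s] %s (%s)%s%s\n", rt$alternative, v, rt$distribution,
      if (length(rt$mean_shifters)) {
        paste0("; z: ", paste(rt$mean_shifters, collapse = ", "))
      } else "",
      if (length(rt$sd_shifters)) {
        paste0("; w: ", paste(rt$sd_shifters, collapse = ", "))
      } else ""
    ))
  }
  cat(sprintf(
    "  %d parameters; %d Halton draws (discard %d)\n",
    n_parameters(x), x$n_draws, x$discard
  ))
  invisible(x)
}
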