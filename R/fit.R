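# Simulated maximum likelihood for the random-parameters multinomial logit
# with heterogeneity in means and variances.
#
# Likelihood: P_n(k) = integral of softmax_k(V_n(beta)) over the mixing
# distribution, approximated by averaging over Halton draws; coefficients
# realised per draw as beta + delta.z + sigma*exp(omega.w)*v.  The gradient
# is computed analytically alongside the likelihood (exact for the
# simulated objective), which keeps the quasi-Newton search cheap and
# stable; a finite-difference check lives in the test suite.

PROB_FLOOR <- 1e-300

#' Multinomial choice probabilities from utilities
#'
#' Softmax across alternatives, guarded against overflow by subtracting the
#' row maximum.  Probabilities sum to one in every row.
#'
#' @param utilities Numeric matrix (observations x alternatives) or vector
#'   of utilities for one observation.
#' @return Matrix of probabilities with the same shape and dimnames.
#' @examples
#' choice_probabilities(c(log(2), 0, 0)) # 0.5 0.25 0.25
#' @export
choice_probabilities <- function(utilities) {
  if (is.null(dim(utilities))) {
    utilities <- matrix(utilities, nrow = 1,
                        dimnames = list(NULL, names(utilities)))
    drop_row <- TRUE
  } else {
    drop_row <- FALSE
  }
  if (any(!is.finite(utilities))) {
    abort("Utilities must be finite (NaN/Inf encountered).")
  }
  e <- exp(utilities - apply(utilities, 1, max))
  p <- e / rowSums(e)
  if (drop_row) p[1, ] else p
}

# --- model-data preparation -------------------------------------------------

prepare_model_data <- function(data, spec) {
  vars <- spec_variables(spec)
  missing_vars <- setdiff(vars, names(data))
  if (length(missing_vars) > 0) {
    abort(sprintf(
      "`data` lacks column(s) required by the model spec: %s.",
      paste(missing_vars, collapse = ", ")
    ))
  }
  if (identical(sort(spec$alternatives), sort(SEVERITY_LEVELS))) {
    sev <- as.character(resolve_severity(data))
  } else {
    if (!"severity" %in% names(data)) {
      abort("`data` needs a `severity` column matching the spec alternatives.")
    }
    sev <- as.character(data$severity)
  }
  y <- match(sev, spec$alternatives)
  if (anyNA(y)) {
    abort("`severity` contains levels outside the spec's alternatives.")
  }
  n <- nrow(data)
  J <- length(spec$alternatives)
  layout <- spec$layout
  X <- lapply(setNames(vars, vars), function(v) {
    col <- as.numeric(data[[v]])
    if (anyNA(col)) abort(sprintf("Column `%s` contains NA.", v))
    col
  })
  # fixed part bookkeeping: parameter index -> (alt index, covariate)
  fix_rows <- which(layout$role %in% c("constant", "fixed"))
  fix_alt <- match(layout$alternative[fix_rows], spec$alternatives)
  fix_x <- lapply(fix_rows, function(i) {
    if (layout$role[i] == "constant") NULL else X[[layout$variable[i]]]
  })
  # random-term bookkeeping
  rterms <- lapply(names(spec$random), function(v) {
    rt <- spec$random[[v]]
    list(
      variable = v,
      alt = match(rt$alternative, spec$alternatives),
      distribution = rt$distribution,
      x = X[[v]],
      Z = if (length(rt$mean_shifters)) {
        do.call(cbind, X[rt$mean_shifters])
      },
      W = if (length(rt$sd_shifters)) {
        do.call(cbind, X[rt$sd_shifters])
      },
      i_mean = which(layout$name == paste0("mean:", v)),
      i_delta = which(layout$role == "delta" & layout$variable == v),
      i_sigma = which(layout$name == paste0("sigma:", v)),
      i_omega = which(layout$role == "omega" & layout$variable == v)
    )
  })
  list(
    y = y, n = n, J = J, X = X,
    ymask = lapply(seq_len(J), function(j) as.numeric(y == j)),
    fix_rows = fix_rows, fix_alt = fix_alt, fix_x = fix_x,
    rterms = rterms, n_par = nrow(layout)
  )
}

# draw transform t(v) and its role in beta = mu + sd * t (normal, uniform,
# triangular); lognormal handled separately as exp(mu + sd v)
transform_draws <- function(v, distribution) {
  switch(distribution,
    normal = ,
    lognormal = v,
    uniform = 2 * pnorm(v) - 1,
    triangular = {
      u <- pnorm(v)
      ifelse(u < 0.5, sqrt(2 * u) - 1, 1 - sqrt(2 * (1 - u)))
    }
  )
}

# Core: simulated log-likelihood and (optionally) per-observation scores.
mixl_eval <- function(theta, md, cube = NULL, want_scores = FALSE,
                      warn_floor = TRUE) {
  n <- md$n
  J <- md$J
  K <- length(md$rterms)
  R <- if (K > 0) dim(cube)[2] else 1L
  # systematic fixed part
  vfix <- matrix(0, n, J)
  for (idx in seq_along(md$fix_rows)) {
    i <- md$fix_rows[idx]
    a <- md$fix_alt[idx]
    x <- md$fix_x[[idx]]
    vfix[, a] <- vfix[, a] + if (is.null(x)) theta[i] else theta[i] * x
  }
  # utilities per alternative as n x R matrices
  U <- lapply(seq_len(J), function(j) matrix(vfix[, j], n, R))
  rinfo <- vector("list", K)
  for (k in seq_len(K)) {
    rt <- md$rterms[[k]]
    mu <- rep(theta[rt$i_mean], n)
    if (!is.null(rt$Z)) {
      mu <- mu + drop(rt$Z %*% theta[rt$i_delta])
    }
    scale <- if (!is.null(rt$W)) {
      exp(drop(rt$W %*% theta[rt$i_omega]))
    } else {
      rep(1, n)
    }
    s_raw <- theta[rt$i_sigma]
    sdv <- abs(s_raw) * scale
    Tk <- transform_draws(cube[, , k, drop = TRUE], rt$distribution)
    if (R == 1L) Tk <- matrix(Tk, n, 1L)
    if (rt$distribution == "lognormal") {
      beta <- exp(mu + sdv * Tk)
      dmu <- beta          # d beta / d mu
      dsd <- Tk * beta     # d beta / d sd
    } else {
      beta <- mu + sdv * Tk
      dmu <- NULL          # constant 1
      dsd <- Tk
    }
    U[[rt$alt]] <- U[[rt$alt]] + rt$x * beta
    rinfo[[k]] <- list(scale = scale, sdv = sdv, sign = sign(s_raw),
                       dmu = dmu, dsd = dsd)
  }
  M <- Reduce(pmax, U)
  E <- lapply(U, function(u) exp(u - M))
  denom <- Reduce(`+`, E)
  P <- lapply(E, function(e) e / denom)
  pch <- 0
  for (j in seq_len(J)) pch <- pch + md$ymask[[j]] * P[[j]]
  pbar <- if (R == 1L) pch[, 1] else rowMeans(pch)
  floored <- pbar < PROB_FLOOR
  if (any(floored)) {
    if (warn_floor) {
      warn(sprintf(
        "%d observation(s) had simulated probability below %.0e; floored.",
        sum(floored), PROB_FLOOR
      ))
    }
    pbar <- pmax(pbar, PROB_FLOOR)
  }
  ll <- sum(log(pbar))
  if (!want_scores) {
    return(list(ll = ll))
  }
  # per-observation scores: d ll_n / d theta
  B <- lapply(seq_len(J), function(j) pch * (md$ymask[[j]] - P[[j]]))
  rb <- vapply(B, function(b) if (R == 1L) b[, 1] else rowSums(b),
               numeric(n)) # n x J
  S <- matrix(0, n, md$n_par)
  for (idx in seq_along(md$fix_rows)) {
    i <- md$fix_rows[idx]
    a <- md$fix_alt[idx]
    x <- md$fix_x[[idx]]
    S[, i] <- if (is.null(x)) rb[, a] else x * rb[, a]
  }
  for (k in seq_len(K)) {
    rt <- md$rterms[[k]]
    ri <- rinfo[[k]]
    Bk <- B[[rt$alt]]
    r_mu <- if (is.null(ri$dmu)) rb[, rt$alt] else rowSums(ri$dmu * Bk)
    r_sd <- rowSums(ri$dsd * Bk)
    S[, rt$i_mean] <- rt$x * r_mu
    for (l in seq_along(rt$i_delta)) {
      S[, rt$i_delta[l]] <- rt$Z[, l] * rt$x * r_mu
    }
    S[, rt$i_sigma] <- ri$sign * ri$scale * rt$x * r_sd
    for (l in seq_along(rt$i_omega)) {
      S[, rt$i_omega[l]] <- rt$W[, l] * ri$sdv * rt$x * r_sd
    }
  }
  S <- S / (R * pbar)
  list(ll = ll, scores = S, gradient = colSums(S))
}

#' Simulated log-likelihood at a parameter vector
#'
#' Evaluates the simulated log-likelihood of the mixed logit: for each
#' observation, the log of the draw-average probability of its observed
#' severity class, with per-draw coefficients realised from the
#' heterogeneity-in-means-and-variances construction.
#'
#' @param theta Packed parameter vector (see [pack_parameters()]).
#' @param data Crash-record data frame (severity + indicator columns).
#' @param spec An [ml_spec()].
#' @param cube Optional [halton_cube()]; built from the spec's draw
#'   settings when omitted.
#' @return The log-likelihood (scalar).
#' @export
simulated_loglik <- function(theta, data, spec, cube = NULL) {
  md <- prepare_model_data(data, spec)
  K <- length(md$rterms)
  if (K > 0 && is.null(cube)) {
    cube <- halton_cube(md$n, spec$n_draws, K, spec$discard,
                        scramble = spec$scramble,
                        seed = if (spec$scramble) 1L else NULL)
  }
  if (K > 0) check_cube(cube, md, spec)
  mixl_eval(pack_check(theta, spec), md, cube)$ll
}

pack_check <- function(theta, spec) {
  if (is.list(theta) ||
      (!is.null(names(theta)) && all(names(theta) %in% spec$layout$name))) {
    return(pack_parameters(spec, theta))
  }
  if (length(theta) != nrow(spec$layout)) {
    abort(sprintf("`theta` must have length %d.", nrow(spec$layout)))
  }
  as.numeric(theta)
}

check_cube <- function(cube, md, spec) {
  d <- dim(cube)
  if (d[1] != md$n || d[3] != length(md$rterms)) {
    abort(sprintf(
      "Draw cube is %d x %d x %d but the data/spec require %d obs x . x %d dims.",
      d[1], d[2], d[3], md$n, length(md$rterms)
    ))
  }
  invisible(cube)
}

#' Null log-likelihood of a discrete-outcome model
#'
#' Two conventions are provided.  `equal_shares` is the log-likelihood with
#' all parameters zero, `-n log(n_alternatives)`; `constants_only` is the
#' maximum for a constants-only model, `sum_k n_k log(n_k / n)` at the
#' empirical class shares (zero-share classes contribute 0 by convention).
#'
#' @param n Number of observations.
#' @param mode `"equal_shares"` (default) or `"constants_only"`.
#' @param shares Empirical class shares (required for `constants_only`;
#'   normalised to sum to one).
#' @param n_alternatives Number of outcome classes (default 3).
#' @return The null log-likelihood (scalar, <= 0).
#' @examples
#' null_loglik(6943) # -6943 * log(3)
#' @export
null_loglik <- function(n, mode = c("equal_shares", "constants_only"),
                        shares = NULL, n_alternatives = 3) {
  n <- check_count(n, "n")
  mode <- match.arg(mode)
  if (mode == "equal_shares") {
    if (!is.null(shares)) {
      abort("`shares` is only used with mode = 'constants_only'.")
    }
    return(-n * log(n_alternatives))
  }
  if (is.null(shares)) {
    abort("mode = 'constants_only' requires `shares`.")
  }
  if (any(shares < 0)) abort("`shares` must be non-negative.")
  s <- shares / sum(shares)
  if (any(s == 0)) {
    inform("Zero empirical share(s): contribute 0 to the null log-likelihood.")
  }
  n * sum(ifelse(s > 0, s * log(s), 0))
}

#' McFadden pseudo R-squared
#'
#' `1 - ll_converged / ll_zero`: the proportional improvement of the fitted
#' model's log-likelihood over the null.
#'
#' @param ll_converged Log-likelihood at convergence (negative).
#' @param ll_zero Null log-likelihood (negative, nonzero).
#' @return Scalar in \[0, 1) when the null is nested in the fitted model.
#' @examples
#' pseudo_r2(-4480.001, -7627.665) # 0.413
#' @export
pseudo_r2 <- function(ll_converged, ll_zero) {
  check_scalar_number(ll_converged, "ll_converged", upper = 0)
  check_scalar_number(ll_zero, "ll_zero", upper = 0)
  if (ll_zero == 0) abort("`ll_zero` must be nonzero.")
  1 - ll_converged / ll_zero
}

#' Population share with a positive (or negative) coefficient
#'
#' For a normally distributed random coefficient with the given mean and
#' standard deviation, the percentage of observations for which the
#' coefficient is positive is `100 * pnorm(mean / sd)`; the negative share
#' is its complement.
#'
#' @param mean Coefficient mean(s).
#' @param sd Coefficient standard deviation(s), strictly positive.
#' @param sign `"positive"` or `"negative"`.
#' @return Tibble with `mean`, `sd`, `sign`, `share_pct` (raw percent) and
#'   `share_pct_rounded` (half-up to one decimal).
#' @examples
#' share_sign(-1.010, 2.210, "positive") # 32.4% of observations
#' @export
share_sign <- function(mean, sd, sign = c("positive", "negative")) {
  sign <- match.arg(sign)
  if (any(!is.finite(sd)) || any(sd <= 0)) {
    abort("`sd` must be strictly positive.")
  }
  z <- mean / sd
  pct <- 100 * pnorm(if (sign == "positive") z else -z)
  tibble::tibble(
    mean = mean, sd = sd, sign = sign,
    share_pct = pct, share_pct_rounded = round_half_up(pct, 1)
  )
}

# --- fitting ----------------------------------------------------------------

#' Fit the mixed logit by simulated maximum likelihood
#'
#' Maximises the simulated log-likelihood with BFGS using the analytic
#' score, holding the Halton draw cube fixed across evaluations (common
#' random numbers).  Standard errors come from the inverse of the
#' numerically differenced Hessian at the optimum, falling back to the
#' BHHH outer product of per-observation scores when the Hessian is not
#' invertible; if both fail, standard errors are reported as `NA`, never
#' fabricated.  The sigma parameters are estimated unconstrained and
#' reported on the positive scale.
#'
#' @param data Crash-record data frame: a `severity` column (or
#'   `severity_kabco`) plus the indicator columns the spec names.
#' @param spec An [ml_spec()].
#' @param start Optional starting values (named vector or list, see
#'   [pack_parameters()]).
#' @param cube Optional pre-built [halton_cube()] (shared draws across
#'   model comparisons); defaults to the spec's draw settings.
#' @param ll_zero_mode Null log-likelihood convention used for the reported
#'   pseudo R-squared; both values are stored either way.
#' @param compute_se Set `FALSE` to skip the Hessian (e.g. inside
#'   simulation studies that only need point estimates).
#' @return A `mixl_fit` object; see [tidy.mixl_fit()] and
#'   [glance.mixl_fit()].
#' @examples
#' tr <- true_params(constants = c(NI = 1.5),
#'                   fixed = list(SI = c(rollover = 1.2)))
#' d <- simulate_outcomes(generate_design(400, c(rollover = 0.2), seed = 1),
#'                        tr, seed = 2)
#' fit <- fit_mixed_logit(d, as_ml_spec(tr))
#' glance(fit)
#' @export
fit_mixed_logit <- function(data, spec, start = NULL, cube = NULL,
                            ll_zero_mode = c("equal_shares", "constants_only"),
                            compute_se = TRUE) {
  stopifnot(inherits(spec, "ml_spec"))
  ll_zero_mode <- match.arg(ll_zero_mode)
  md <- prepare_model_data(data, spec)
  K <- length(md$rterms)
  if (md$n < md$n_par) {
    abort(sprintf(
      "Data has %d observations for %d parameters.", md$n, md$n_par
    ))
  }
  if (K > 0) {
    if (is.null(cube)) {
      cube <- halton_cube(md$n, spec$n_draws, K, spec$discard,
                          scramble = spec$scramble,
                          seed = if (spec$scramble) 1L else NULL)
    }
    check_cube(cube, md, spec)
  }
  theta0 <- if (is.null(start)) {
    pack_parameters(spec)
  } else if (is.numeric(start) && is.null(names(start)) &&
             length(start) == md$n_par) {
    as.numeric(start)
  } else {
    pack_parameters(spec, start)
  }
  # cache: optim calls fn and gr back-to-back at the same theta
  last <- new.env(parent = emptyenv())
  evaluate <- function(theta) {
    if (!is.null(last$theta) && identical(theta, last$theta)) {
      return(last$res)
    }
    res <- mixl_eval(theta, md, cube, want_scores = TRUE, warn_floor = FALSE)
    last$theta <- theta
    last$res <- res
    res
  }
  negll <- function(theta) -evaluate(theta)$ll
  neggr <- function(theta) -evaluate(theta)$gradient
  opt <- optim(
    theta0, fn = negll, gr = neggr, method = "BFGS",
    control = list(maxit = spec$control$max_iter,
                   reltol = spec$control$reltol)
  )
  # restart from the stopping point (fresh Hessian approximation) while the
  # score is not yet flat; reltol can trigger early on shallow objectives
  restarts <- 0L
  while (restarts < 3L &&
         max(abs(mixl_eval(opt$par, md, cube, want_scores = TRUE,
                           warn_floor = FALSE)$gradient)) >
           spec$control$grad_tol) {
    opt2 <- optim(
      opt$par, fn = negll, gr = neggr, method = "BFGS",
      control = list(maxit = spec$control$max_iter,
                     reltol = spec$control$reltol)
    )
    improved <- opt2$value < opt$value - 1e-12
    if (opt2$value <= opt$value) opt <- opt2
    if (!improved) break
    restarts <- restarts + 1L
  }
  theta_hat <- opt$par
  at_opt <- mixl_eval(theta_hat, md, cube, want_scores = TRUE)
  grad_norm <- max(abs(at_opt$gradient))
  converged <- opt$convergence == 0
  if (!converged) {
    warn(sprintf(
      "Optimiser did not report convergence (code %d: %s); partial results retained.",
      opt$convergence, opt$message %||% "no message"
    ))
  }
  se <- rep(NA_real_, md$n_par)
  vcov <- NULL
  se_method <- "none"
  if (compute_se) {
    H <- tryCatch(
      optimHess(theta_hat, fn = negll, gr = neggr),
      error = function(e) NULL
    )
    if (!is.null(H)) {
      vcov <- tryCatch({
        V <- solve(H)
        if (any(diag(V) <= 0)) NULL else V
      }, error = function(e) NULL)
      if (!is.null(vcov)) se_method <- "hessian"
    }
    if (is.null(vcov)) {
      vcov <- tryCatch({
        V <- solve(crossprod(at_opt$scores))
        if (any(diag(V) <= 0)) NULL else V
      }, error = function(e) NULL)
      if (!is.null(vcov)) se_method <- "bhhh"
    }
    if (is.null(vcov)) {
      warn("Curvature is singular at the optimum; standard errors unavailable.")
    } else {
      se <- sqrt(diag(vcov))
    }
  }
  estimates <- unpack_parameters(spec, theta_hat)
  estimates$std_error <- se
  estimates$t_stat <- estimates$value / se
  # 90% two-tailed screening flag, the conventional retention threshold
  estimates$significant_90 <- !is.na(estimates$t_stat) &
    abs(estimates$t_stat) > qnorm(0.95)
  shares <- tabulate(md$y, nbins = md$J)
  ll_zero_equal <- -md$n * log(md$J)
  ll_zero_const <- null_loglik(md$n, "constants_only", shares = shares,
                               n_alternatives = md$J)
  ll_zero <- if (ll_zero_mode == "equal_shares") ll_zero_equal else ll_zero_const
  structure(
    list(
      spec = spec,
      estimates = estimates,
      theta = theta_hat,
      vcov = vcov,
      se_method = se_method,
      ll = at_opt$ll,
      ll_zero = ll_zero,
      ll_zero_mode = ll_zero_mode,
      ll_zero_equal_shares = ll_zero_equal,
      ll_zero_constants_only = ll_zero_const,
      pseudo_r2 = pseudo_r2(at_opt$ll, ll_zero),
      n_obs = md$n,
      n_draws = if (K > 0) dim(cube)[2] else 0L,
      discard = spec$discard,
      class_counts = setNames(shares, spec$alternatives),
      convergence = list(
        converged = converged, code = opt$convergence,
        iterations = opt$counts[["function"]],
        gradient_norm = grad_norm,
        gradient_ok = grad_norm < spec$control$grad_tol
      ),
      data = tibble::as_tibble(data)
    ),
    class = "mixl_fit"
  )
}

#' @export
print.mixl_fit <- function(x, ...) {
  cat(sprintf(
    "<mixl_fit> %d obs, %d parameters, %s\n",
    x$n_obs, length(x$theta),
    if (x$n_draws > 0) sprintf("%d Halton draws", x$n_draws) else "no random terms"
  ))
  cat(sprintf(
    "  log-likelihood %.3f (null %.3f, %s); pseudo R-sq %.3f\n",
    x$ll, x$ll_zero, x$ll_zero_mode, x$pseudo_r2
  ))
  cat(sprintf(
    "  converged: %s (gradient max-norm %.2e)\n",
    x$convergence$converged, x$convergence$gradient_norm
  ))
  print(tidy(x), n = 15)
  invisible(x)
}
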