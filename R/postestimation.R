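# Post-estimation: average discrete-change marginal effects, the
# likelihood-ratio transferability test, chi-square critical values.

# Per-observation "mean" coefficients: random terms collapsed to their
# distribution mean (beta + delta.z for normal/uniform/triangular;
# exp(mu + sd^2/2) for lognormal), simulation noise dropped.
mean_utilities <- function(data, spec, theta, include_mean_shifters = TRUE) {
  md <- prepare_model_data(data, spec)
  vfix <- matrix(0, md$n, md$J,
                 dimnames = list(NULL, spec$alternatives))
  for (idx in seq_along(md$fix_rows)) {
    i <- md$fix_rows[idx]
    a <- md$fix_alt[idx]
    x <- md$fix_x[[idx]]
    vfix[, a] <- vfix[, a] + if (is.null(x)) theta[i] else theta[i] * x
  }
  for (rt in md$rterms) {
    mu <- rep(theta[rt$i_mean], md$n)
    if (!is.null(rt$Z) && include_mean_shifters) {
      mu <- mu + drop(rt$Z %*% theta[rt$i_delta])
    }
    if (rt$distribution == "lognormal") {
      scale <- if (!is.null(rt$W)) {
        exp(drop(rt$W %*% theta[rt$i_omega]))
      } else {
        rep(1, md$n)
      }
      sdv <- abs(theta[rt$i_sigma]) * scale
      mu <- exp(mu + sdv^2 / 2)
    }
    vfix[, rt$alt] <- vfix[, rt$alt] + mu * rt$x
  }
  vfix
}

#' Average discrete-change marginal effects
#'
#' For each indicator variable of the model, the effect on each severity
#' probability of flipping the indicator from 0 to 1 while every other
#' covariate keeps its observed value, averaged over the estimation sample.
#' Random coefficients are evaluated at their estimated means; by default
#' the mean includes the heterogeneity-in-mean shift `delta . z` of each
#' observation (set `include_mean_shifters = FALSE` for the strict
#' grand-mean behaviour).  Each row's three effects sum to zero because the
#' probabilities sum to one in both counterfactuals.
#'
#' @param fit A [fit_mixed_logit()] result.
#' @param data Data to average over (defaults to the estimation sample).
#' @param variables Indicator variables to evaluate (defaults to every
#'   variable entering a utility).
#' @param include_mean_shifters Logical, see above.
#' @return Tibble of class `marginal_effects`: `variable`, `defined_for`,
#'   one `me_<alternative>` column per alternative (raw values; round for
#'   display with [round_half_up()]).
#' @export
marginal_effects <- function(fit, data = fit$data, variables = NULL,
                             include_mean_shifters = TRUE) {
  stopifnot(inherits(fit, "mixl_fit"))
  spec <- fit$spec
  utility_vars <- c(unlist(spec$fixed, use.names = FALSE), names(spec$random))
  variables <- variables %||% utility_vars
  defined_for <- c(
    setNames(
      rep(names(spec$fixed), lengths(spec$fixed)),
      unlist(spec$fixed, use.names = FALSE)
    ),
    vapply(spec$random, `[[`, character(1), "alternative")
  )
  for (v in variables) {
    if (!v %in% names(data)) {
      abort(sprintf("Variable `%s` is not a column of `data`.", v))
    }
    vals <- unique(as.numeric(data[[v]]))
    if (!all(vals %in% c(0, 1))) {
      abort(sprintf(
        "Marginal effects require binary indicators; `%s` is not 0/1.", v
      ))
    }
  }
  if (!include_mean_shifters) {
    inform("Marginal effects computed at grand-mean coefficients (delta.z ignored).")
  }
  probs_at <- function(d) {
    choice_probabilities(
      mean_utilities(d, spec, fit$theta, include_mean_shifters)
    )
  }
  rows <- purrr::map(variables, function(v) {
    d1 <- d0 <- data
    d1[[v]] <- 1
    d0[[v]] <- 0
    eff <- colMeans(probs_at(d1)) - colMeans(probs_at(d0))
    tibble::tibble(
      variable = v,
      defined_for = unname(defined_for[v]) %||% NA_character_,
      !!!setNames(as.list(eff), paste0("me_", spec$alternatives))
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("marginal_effects", class(out))
  out
}

#' Chi-square quantile (critical value)
#'
#' @param df Degrees of freedom (>= 1).
#' @param p Probability level in (0, 1).
#' @return The inverse chi-square CDF at `p`.
#' @examples
#' chi2_quantile(15, 0.9999) # 44.26
#' @export
chi2_quantile <- function(df, p) {
  df <- check_count(df, "df")
  check_scalar_number(p, "p")
  if (p <= 0 || p >= 1) {
    abort("`p` must lie strictly inside (0, 1).")
  }
  qchisq(p, df)
}

#' Likelihood-ratio test for separate group models (transferability)
#'
#' Tests whether estimating separate models for two groups of crashes
#' (e.g. in-state versus out-of-state drivers) is statistically justified
#' against one pooled model:
#' `LR = -2 * (LL_pooled - LL_group1 - LL_group2)`, chi-square distributed
#' with degrees of freedom equal to the total parameters of the separate
#' models minus those of the pooled model.
#'
#' @param ll_pooled Converged log-likelihood of the pooled model, or a
#'   `mixl_fit` (then `ll_group1`/`ll_group2` must be fits too and `df` is
#'   derived from the parameter counts).
#' @param ll_group1,ll_group2 Converged group log-likelihoods (or fits).
#' @param df Degrees of freedom (required when passing raw numbers).
#' @param confidence Confidence level for the critical value.
#' @return One-row tibble: `lr_statistic`, `df`, `confidence`,
#'   `critical_value`, `separate_models_supported`.
#' @examples
#' lr_transferability(-8000, -4480.001, -3935.43, df = 15,
#'                    confidence = 0.9999)
#' @export
lr_transferability <- function(ll_pooled, ll_group1, ll_group2, df = NULL,
                               confidence = 0.95) {
  if (inherits(ll_pooled, "mixl_fit")) {
    stopifnot(inherits(ll_group1, "mixl_fit"), inherits(ll_group2, "mixl_fit"))
    df <- df %||%
      (length(ll_group1$theta) + length(ll_group2$theta) - length(ll_pooled$theta))
    ll_group1 <- ll_group1$ll
    ll_group2 <- ll_group2$ll
    ll_pooled <- ll_pooled$ll
  }
  if (is.null(df)) {
    abort("`df` is required when log-likelihoods are given as numbers.")
  }
  df <- check_count(df, "df")
  check_scalar_number(confidence, "confidence")
  if (confidence <= 0 || confidence >= 1) {
    abort("`confidence` must lie strictly inside (0, 1).")
  }
  lr <- -2 * (ll_pooled - ll_group1 - ll_group2)
  if (lr < 0) {
    warn(sprintf(
      "Negative LR statistic (%.4f): the pooled model is not nested within the separate fits up to simulation noise. Reported as-is.",
      lr
    ))
  }
  crit <- chi2_quantile(df, confidence)
  tibble::tibble(
    lr_statistic = lr,
    df = df,
    confidence = confidence,
    critical_value = crit,
    separate_models_supported = lr > crit
  )
}
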