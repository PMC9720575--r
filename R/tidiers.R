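# broom-style accessors and ggplot2 methods for fitted objects.

#' Tidy a fitted mixed logit
#'
#' @param x A `mixl_fit`.
#' @param ... Unused.
#' @return Tibble with one row per parameter: `term`, `role`, `variable`,
#'   `alternative`, `shifter`, `estimate` (sigma on the positive scale),
#'   `std.error`, `statistic` (t), `significant_90` (90% two-tailed
#'   screening flag).
#' @method tidy mixl_fit
#' @export
tidy.mixl_fit <- function(x, ...) {
  dplyr::transmute(
    x$estimates,
    term = .data$name,
    role = .data$role,
    variable = .data$variable,
    alternative = .data$alternative,
    shifter = .data$shifter,
    estimate = .data$value,
    std.error = .data$std_error,
    statistic = .data$t_stat,
    significant_90 = .data$significant_90
  )
}

#' One-row summary of a fitted mixed logit
#'
#' @param x A `mixl_fit`.
#' @param ... Unused.
#' @return Tibble: `n_obs`, `n_parameters`, `n_draws`, `logLik`,
#'   `null_logLik`, `null_mode`, `pseudo_r_squared`, `converged`,
#'   `iterations`, `gradient_norm`.
#' @method glance mixl_fit
#' @export
glance.mixl_fit <- function(x, ...) {
  tibble::tibble(
    n_obs = x$n_obs,
    n_parameters = length(x$theta),
    n_draws = x$n_draws,
    logLik = x$ll,
    null_logLik = x$ll_zero,
    null_mode = x$ll_zero_mode,
    pseudo_r_squared = x$pseudo_r2,
    converged = x$convergence$converged,
    iterations = x$convergence$iterations,
    gradient_norm = x$convergence$gradient_norm
  )
}

#' Coefficient plot for a fitted mixed logit
#'
#' Point estimates with 95% normal-theory intervals, faceted by the
#' alternative each term is defined for.
#'
#' @param object A `mixl_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mixl_fit
#' @export
autoplot.mixl_fit <- function(object, ...) {
  td <- tidy(object)
  td$lo <- td$estimate - qnorm(0.975) * td$std.error
  td$hi <- td$estimate + qnorm(0.975) * td$std.error
  ggplot2::ggplot(td, ggplot2::aes(x = .data$estimate,
                                   y = stats::reorder(.data$term, .data$estimate))) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$lo, xmax = .data$hi), height = 0.2, na.rm = TRUE
    ) +
    ggplot2::geom_point() +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$alternative),
                        scales = "free_y", space = "free_y") +
    ggplot2::labs(
      x = "Estimate (95% interval)", y = NULL,
      title = "Mixed logit parameter estimates"
    )
}

#' Bar chart of average marginal effects
#'
#' @param object A [marginal_effects()] table.
#' @param ... Unused.
#' @return A ggplot object: one bar per variable and severity class.
#' @method autoplot marginal_effects
#' @export
autoplot.marginal_effects <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object),
    dplyr::starts_with("me_"),
    names_to = "alternative", names_prefix = "me_", values_to = "effect"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$effect, y = .data$variable,
                                     fill = .data$alternative)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey40") +
    ggplot2::labs(
      x = "Average change in probability (indicator 0 -> 1)",
      y = NULL, fill = "Severity",
      title = "Average discrete-change marginal effects"
    )
}

#' Direction-arrow comparison of two group models
#'
#' Renders the cross-group comparison table: for every variable, an up or
#' down arrow per group giving the sign of its average marginal effect on
#' the probability of the severity class it is defined for.
#'
#' @param me_list Named list of [marginal_effects()] tables, one per group
#'   (e.g. `list(in_state = ..., out_of_state = ...)`).
#' @return Tibble: `variable`, `defined_for`, one arrow column per group
#'   (`"up"`/`"down"` rendered as arrows in `format_` columns).
#' @export
compare_effect_directions <- function(me_list) {
  if (is.null(names(me_list)) || any(!nzchar(names(me_list)))) {
    abort("`me_list` must be a named list of marginal-effects tables.")
  }
  per_group <- purrr::imap(me_list, function(me, group) {
    me <- tibble::as_tibble(me)
    own <- vapply(seq_len(nrow(me)), function(i) {
      col <- paste0("me_", me$defined_for[i])
      if (col %in% names(me)) me[[col]][i] else NA_real_
    }, numeric(1))
    tibble::tibble(
      variable = me$variable, defined_for = me$defined_for,
      !!group := ifelse(own >= 0, "↑", "↓")
    )
  })
  purrr::reduce(per_group, dplyr::full_join, by = c("variable", "defined_for"))
}
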