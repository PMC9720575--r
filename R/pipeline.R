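# File-in / file-out pipeline wrappers: simulate a scenario to disk,
# render descriptive tables, fit per-group models and report.  These are
# the functions the shell entry point (inst/scripts/crashmixl) dispatches
# to; everything they do is available directly through the package API.

#' Simulate a scenario to disk
#'
#' Reads a YAML scenario (or takes a `sim_scenario`), simulates the
#' dataset, and writes `dataset.csv`, the echoed `scenario.yml` and a
#' `truth.csv` of the packed ground-truth parameter vector.  Re-running
#' with the same scenario reproduces the files bit-for-bit.
#'
#' @param scenario Path to a scenario YAML or a `sim_scenario` object.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a named list of the written paths.
#' @export
run_simulate <- function(scenario, out_dir) {
  if (is.character(scenario)) {
    scenario <- read_scenario(scenario)
  }
  stopifnot(inherits(scenario, "sim_scenario"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  data <- simulate_scenario(scenario, kabco = TRUE)
  paths <- list(
    dataset = file.path(out_dir, "dataset.csv"),
    scenario = file.path(out_dir, "scenario.yml"),
    truth = file.path(out_dir, "truth.csv")
  )
  readr::write_csv(tibble::as_tibble(data), paths$dataset, progress = FALSE)
  write_scenario(scenario, paths$scenario)
  tv <- truth_vector(scenario$truth)
  readr::write_csv(
    tibble::tibble(name = names(tv), value = unname(tv)),
    paths$truth, progress = FALSE
  )
  invisible(paths)
}

#' Write descriptive tables for a set of variables
#'
#' One severity cross-tabulation per variable, written as CSV and as
#' aligned plain text.  Unknown variables are listed in the returned
#' report and skipped; the run continues.
#'
#' @param data Crash-record data frame.
#' @param variables Character vector of variables to tabulate.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with `tables` (named list of tibbles) and
#'   `skipped` (unknown variable names).
#' @export
run_describe <- function(data, variables, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  known <- intersect(variables, names(data))
  skipped <- setdiff(variables, known)
  if (length(skipped) > 0) {
    warn(sprintf(
      "Unknown variable(s) skipped: %s.", paste(skipped, collapse = ", ")
    ))
  }
  if (nrow(data) == 0) {
    warn("Empty record set: descriptive tables will be empty.")
  }
  tables <- lapply(setNames(known, known), function(v) {
    tab <- descriptive_table(data, v)
    readr::write_csv(tab, file.path(out_dir, paste0("describe_", v, ".csv")),
                     progress = FALSE)
    writeLines(format_descriptive_table(tab),
               file.path(out_dir, paste0("describe_", v, ".txt")))
    tab
  })
  invisible(list(tables = tables, skipped = skipped))
}

#' Serialise a fitted model to CSV + JSON
#'
#' Writes `<prefix>_estimates.csv` (one row per parameter: name,
#' alternative, estimate, std. error, t, significance flag) and
#' `<prefix>_summary.json` (log-likelihoods, pseudo R-squared, N, draw
#' settings, convergence diagnostics).
#'
#' @param fit A `mixl_fit`.
#' @param out_dir Output directory.
#' @param prefix File-name prefix.
#' @return Invisibly, the two paths.
#' @export
write_fit_result <- function(fit, out_dir, prefix = "fit") {
  stopifnot(inherits(fit, "mixl_fit"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  est_path <- file.path(out_dir, paste0(prefix, "_estimates.csv"))
  sum_path <- file.path(out_dir, paste0(prefix, "_summary.json"))
  readr::write_csv(tidy(fit), est_path, progress = FALSE)
  jsonlite::write_json(
    list(
      log_likelihood = fit$ll,
      null_log_likelihood = fit$ll_zero,
      null_mode = fit$ll_zero_mode,
      null_log_likelihood_equal_shares = fit$ll_zero_equal_shares,
      null_log_likelihood_constants_only = fit$ll_zero_constants_only,
      pseudo_r_squared = fit$pseudo_r2,
      n_obs = fit$n_obs,
      n_draws = fit$n_draws,
      discard = fit$discard,
      se_method = fit$se_method,
      converged = fit$convergence$converged,
      iterations = fit$convergence$iterations,
      gradient_norm = fit$convergence$gradient_norm
    ),
    sum_path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(list(estimates = est_path, summary = sum_path))
}

#' Fit per-group models and report
#'
#' Splits the data on a grouping column (e.g. the `residency` label from
#' [partition_residency()]), fits one model per group, computes marginal
#' effects, and — when two or more groups are present — fits the pooled
#' model and runs the likelihood-ratio transferability test.  All
#' artifacts are written under `out_dir`: per-group estimate CSVs and JSON
#' summaries, marginal-effects CSVs, a direction-arrow comparison table,
#' and `transferability.json`.
#'
#' @param data Crash-record data frame with a grouping column.
#' @param spec An [ml_spec()] (used for every group and the pooled fit).
#' @param group_col Name of the grouping column (default `"residency"`;
#'   a `rejected` level, if present, is excluded with a notice).
#' @param out_dir Output directory.
#' @param confidence Confidence level for the transferability test.
#' @return Invisibly, a list with the per-group fits, marginal effects,
#'   the pooled fit (or `NULL`) and the transferability tibble (or `NULL`).
#' @export
run_fit_report <- function(data, spec, group_col = "residency", out_dir,
                           confidence = 0.9999) {
  if (!group_col %in% names(data)) {
    abort(sprintf("Grouping column `%s` not found in `data`.", group_col))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  groups <- as.character(data[[group_col]])
  if (any(groups == "rejected")) {
    inform(sprintf(
      "Excluding %d rejected record(s) from model fitting.",
      sum(groups == "rejected")
    ))
    data <- data[groups != "rejected", , drop = FALSE]
    groups <- groups[groups != "rejected"]
  }
  levels <- unique(groups)
  fits <- lapply(setNames(levels, levels), function(g) {
    fit_mixed_logit(data[groups == g, , drop = FALSE], spec)
  })
  effects <- lapply(fits, marginal_effects)
  for (g in levels) {
    write_fit_result(fits[[g]], out_dir, prefix = g)
    readr::write_csv(effects[[g]],
                     file.path(out_dir, paste0(g, "_marginal_effects.csv")),
                     progress = FALSE)
  }
  readr::write_csv(compare_effect_directions(effects),
                   file.path(out_dir, "effect_directions.csv"),
                   progress = FALSE)
  pooled <- NULL
  transfer <- NULL
  if (length(levels) >= 2) {
    pooled <- fit_mixed_logit(data, spec)
    write_fit_result(pooled, out_dir, prefix = "pooled")
    df <- sum(vapply(fits, function(f) length(f$theta), integer(1))) -
      length(pooled$theta)
    ll_groups <- vapply(fits, function(f) f$ll, numeric(1))
    transfer <- lr_transferability(
      pooled$ll, ll_groups[1], sum(ll_groups[-1]),
      df = df, confidence = confidence
    )
    jsonlite::write_json(as.list(transfer), file.path(out_dir, "transferability.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    inform("Single group: transferability test skipped.")
  }
  invisible(list(
    fits = fits, effects = effects, pooled = pooled, transferability = transfer
  ))
}
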