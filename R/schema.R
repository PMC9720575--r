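# Crash-record schema: KABCO recoding, residency partition, descriptive
# cross-tabulations, CSV + data-dictionary I/O.

KABCO_CODES <- c("K", "A", "B", "C", "O")
SEVERITY_LEVELS <- c("SI", "MIN", "NI")

#' Recode KABCO injury codes to the three-class severity outcome
#'
#' Collapses the five-level police-reported KABCO scale (K fatal,
#' A incapacitating, B evident, C possible, O no injury) into the three
#' analysis classes used throughout the package: `SI` (severe injury,
#' K + A), `MIN` (minor injury, B + C) and `NI` (no injury, O).
#'
#' @param code Character vector of KABCO letters.
#' @return Factor with levels `SI`, `MIN`, `NI`.
#' @examples
#' recode_kabco(c("K", "A", "B", "C", "O"))
#' @export
recode_kabco <- function(code) {
  code <- toupper(as.character(code))
  bad <- unique(code[!code %in% KABCO_CODES])
  if (length(bad) > 0) {
    abort(sprintf(
      "Unknown KABCO severity code(s): %s. Expected one of %s.",
      paste(dQuote(bad, q = FALSE), collapse = ", "),
      paste(KABCO_CODES, collapse = ", ")
    ))
  }
  out <- dplyr::case_match(
    code,
    c("K", "A") ~ "SI",
    c("B", "C") ~ "MIN",
    "O" ~ "NI"
  )
  factor(out, levels = SEVERITY_LEVELS)
}

#' Partition crash records by truck licensing state
#'
#' Labels each record `in_state` when `license_state` equals `home_state`
#' and `out_of_state` otherwise.  Records with a missing or empty licensing
#' state are labelled `rejected` rather than silently dropped; the counts of
#' all three groups are attached as a load report.
#'
#' @param data Data frame of crash records with a `license_state` column.
#' @param home_state Two-letter code of the home state (e.g. `"AL"`).
#' @param state_col Name of the licensing-state column.
#' @return The input as a tibble with an added `residency` column
#'   (`in_state` / `out_of_state` / `rejected`).  The attribute
#'   `"residency_report"` holds a one-row tibble of group counts.
#' @examples
#' crashes <- tibble::tibble(license_state = c("AL", "GA", "AL", ""))
#' partition_residency(crashes, "AL")
#' @export
partition_residency <- function(data, home_state, state_col = "license_state") {
  if (!state_col %in% names(data)) {
    abort(sprintf("Column `%s` not found in `data`.", state_col))
  }
  if (!is.character(home_state) || length(home_state) != 1L || !nzchar(home_state)) {
    abort("`home_state` must be a single non-empty state code.")
  }
  st <- toupper(trimws(as.character(data[[state_col]])))
  residency <- dplyr::case_when(
    is.na(st) | !nzchar(st) ~ "rejected",
    st == toupper(home_state) ~ "in_state",
    .default = "out_of_state"
  )
  out <- dplyr::mutate(
    tibble::as_tibble(data),
    residency = factor(residency, levels = c("in_state", "out_of_state", "rejected"))
  )
  report <- tibble::tibble(
    home_state = toupper(home_state),
    n_in_state = sum(residency == "in_state"),
    n_out_of_state = sum(residency == "out_of_state"),
    n_rejected = sum(residency == "rejected"),
    n_total = length(residency)
  )
  if (report$n_rejected > 0) {
    inform(sprintf(
      "%d record(s) with missing licensing state routed to the rejected group.",
      report$n_rejected
    ))
  }
  attr(out, "residency_report") <- report
  out
}

resolve_severity <- function(data) {
  if ("severity" %in% names(data)) {
    sev <- as.character(data$severity)
    bad <- unique(sev[!sev %in% SEVERITY_LEVELS])
    if (length(bad) > 0) {
      abort(sprintf(
        "`severity` contains value(s) outside {SI, MIN, NI}: %s",
        paste(bad, collapse = ", ")
      ))
    }
    factor(sev, levels = SEVERITY_LEVELS)
  } else if ("severity_kabco" %in% names(data)) {
    recode_kabco(data$severity_kabco)
  } else {
    abort("`data` needs a `severity` (SI/MIN/NI) or `severity_kabco` column.")
  }
}

#' Descriptive severity cross-tabulation for one variable
#'
#' Cross-tabulates the levels of one categorical (or indicator) variable
#' against the three-class severity outcome, in the layout of printed crash
#' descriptive tables: per level, a count and a row percent for each
#' severity class plus the row total.  Percents are rounded half-up to one
#' decimal; the unrounded proportions are kept in `prop_*` columns.
#'
#' @param data Data frame of crash records carrying either a `severity`
#'   column (SI/MIN/NI) or a `severity_kabco` column.
#' @param variable Name of the variable to tabulate (string).
#' @return A tibble with one row per observed level: `variable`, `level`,
#'   `n_SI`, `pct_SI`, `n_MIN`, `pct_MIN`, `n_NI`, `pct_NI`, `n_total`,
#'   and raw proportions `prop_SI`, `prop_MIN`, `prop_NI`.
#' @examples
#' crashes <- tibble::tibble(
#'   severity_kabco = c("K", "B", "O", "O", "A"),
#'   rural = c(1, 1, 0, 0, 1)
#' )
#' descriptive_table(crashes, "rural")
#' @export
descriptive_table <- function(data, variable) {
  if (!is.character(variable) || length(variable) != 1L) {
    abort("`variable` must be a single column name.")
  }
  if (!variable %in% names(data)) {
    abort(sprintf("Variable `%s` is not a column of `data`.", variable))
  }
  sev <- resolve_severity(data)
  lev <- data[[variable]]
  tab <- table(level = lev, severity = sev)
  counts <- tibble::as_tibble(as.data.frame.matrix(tab), rownames = "level")
  out <- counts |>
    dplyr::rename(n_SI = "SI", n_MIN = "MIN", n_NI = "NI") |>
    dplyr::mutate(
      variable = variable,
      n_total = .data$n_SI + .data$n_MIN + .data$n_NI,
      prop_SI = .data$n_SI / .data$n_total,
      prop_MIN = .data$n_MIN / .data$n_total,
      prop_NI = .data$n_NI / .data$n_total,
      pct_SI = round_half_up(100 * .data$prop_SI, 1),
      pct_MIN = round_half_up(100 * .data$prop_MIN, 1),
      pct_NI = round_half_up(100 * .data$prop_NI, 1)
    ) |>
    dplyr::select(
      "variable", "level", "n_SI", "pct_SI", "n_MIN", "pct_MIN",
      "n_NI", "pct_NI", "n_total", "prop_SI", "prop_MIN", "prop_NI"
    )
  tibble::as_tibble(out)
}

#' Read a data dictionary declaring attribute vocabularies
#'
#' The dictionary is a YAML file mapping attribute names to the vector of
#' admissible levels, e.g. `primary_contributing_factor: [Fatigue, Speeding]`.
#' Indicator variables may be declared as `[0, 1]`.
#'
#' @param path Path to the YAML dictionary.
#' @return Named list of character vectors (attribute vocabularies).
#' @export
read_data_dictionary <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Data dictionary `%s` does not exist.", path))
  }
  dict <- yaml::read_yaml(path)
  if (!is.list(dict) || is.null(names(dict)) || any(!nzchar(names(dict)))) {
    abort("The data dictionary must be a named mapping of attribute -> levels.")
  }
  lapply(dict, as.character)
}

#' Read crash records from CSV with optional vocabulary validation
#'
#' Reads a crash-record table (one row per crash).  When a data dictionary
#' is supplied, rows whose attribute levels fall outside the declared
#' vocabulary — or whose KABCO code is invalid — are quarantined into the
#' `"quarantined"` attribute and reported, never silently dropped.
#'
#' @param path CSV path.  A `severity_kabco` column is expected; a
#'   `license_state` column is used by [partition_residency()].
#' @param dictionary Optional named list of vocabularies (see
#'   [read_data_dictionary()]); only columns named in it are validated.
#' @return Tibble of valid records with a `severity` factor column added.
#'   Attributes: `"quarantined"` (tibble of rejected rows with a `reason`
#'   column) and `"load_report"` (row counts).
#' @export
read_crash_csv <- function(path, dictionary = NULL) {
  data <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!"severity_kabco" %in% names(data)) {
    abort("Crash CSV must contain a `severity_kabco` column.")
  }
  reason <- rep(NA_character_, nrow(data))
  code <- toupper(as.character(data$severity_kabco))
  bad_sev <- is.na(code) | !code %in% KABCO_CODES
  reason[bad_sev] <- paste0("invalid severity_kabco: ", data$severity_kabco[bad_sev])
  if (!is.null(dictionary)) {
    for (var in intersect(names(dictionary), names(data))) {
      lev <- as.character(data[[var]])
      bad <- !is.na(lev) & !lev %in% dictionary[[var]] & is.na(reason)
      reason[bad] <- paste0("invalid level for ", var, ": ", lev[bad])
    }
  }
  keep <- is.na(reason)
  quarantined <- dplyr::mutate(data[!keep, , drop = FALSE], reason = reason[!keep])
  out <- data[keep, , drop = FALSE]
  out$severity <- recode_kabco(out$severity_kabco)
  if (nrow(quarantined) > 0) {
    warn(sprintf(
      "%d record(s) quarantined during load (see attr(., 'quarantined')).",
      nrow(quarantined)
    ))
  }
  attr(out, "quarantined") <- tibble::as_tibble(quarantined)
  attr(out, "load_report") <- tibble::tibble(
    n_read = nrow(data), n_valid = nrow(out), n_quarantined = nrow(quarantined)
  )
  out
}

#' Render a descriptive table as aligned plain text
#'
#' @param table A tibble from [descriptive_table()].
#' @return Character vector of lines (invisibly printable with `cat`).
#' @export
format_descriptive_table <- function(table) {
  disp <- table |>
    dplyr::transmute(
      Level = .data$level,
      `SI n` = .data$n_SI, `SI %` = sprintf("%.1f", .data$pct_SI),
      `MIN n` = .data$n_MIN, `MIN %` = sprintf("%.1f", .data$pct_MIN),
      `NI n` = .data$n_NI, `NI %` = sprintf("%.1f", .data$pct_NI),
      Total = .data$n_total
    )
  cells <- do.call(cbind, lapply(disp, function(col) {
    if (length(col) == 0) character(0) else format(as.character(col))
  }))
  mat <- rbind(names(disp), cells)
  widths <- apply(nchar(mat), 2, max)
  lines <- apply(mat, 1, function(row) {
    paste(mapply(formatC, row, width = widths), collapse = "  ")
  })
  c(paste0("Variable: ", table$variable[1]), unname(lines))
}
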