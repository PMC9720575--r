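# Shared helpers: rounding convention, prime tests, argument checks.

#' Round half away from zero
#'
#' Printed crash tables round percentages with the "half-up" convention
#' (0.05 -> 0.1), not the IEEE round-half-even rule that base [round()]
#' applies.  Used wherever the package renders a percentage or a marginal
#' effect for display; raw values are always retained alongside.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector rounded half away from zero.
#' @examples
#' round_half_up(c(0.05, 0.15, -0.05), 1)
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

is_prime <- function(n) {
  if (length(n) != 1L || is.na(n) || n != floor(n) || n < 2) {
    return(FALSE)
  }
  if (n < 4) {
    return(TRUE)
  }
  if (n %% 2 == 0) {
    return(FALSE)
  }
  if (n < 9) {
    return(TRUE)
  }
  all(n %% seq(3, floor(sqrt(n)), by = 2) != 0)
}

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single number.", name))
  }
  if (x < lower || x > upper) {
    abort(sprintf("`%s` must be in [%s, %s], got %s.", name, lower, upper, x))
  }
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  check_scalar_number(x, name, lower = min)
  if (x != floor(x)) {
    abort(sprintf("`%s` must be an integer, got %s.", name, x))
  }
  invisible(as.integer(x))
}
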