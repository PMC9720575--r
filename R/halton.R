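# Halton quasi-random draw machinery for simulated maximum likelihood.

# First 25 primes; one low-discrepancy dimension per random coefficient.
HALTON_PRIMES <- c(
  2L, 3L, 5L, 7L, 11L, 13L, 17L, 19L, 23L, 29L, 31L, 37L, 41L, 43L,
  47L, 53L, 59L, 61L, 67L, 71L, 73L, 79L, 83L, 89L, 97L
)

#' Halton sequence (radical inverse) in a prime base
#'
#' Deterministic low-discrepancy sequence on (0, 1): the n-th point is the
#' radical inverse of n in the given base (digits of n reflected about the
#' radix point).  The first `discard` points can be dropped to skip the
#' coarse, highly structured prefix of the sequence.
#'
#' @param n Number of points to return.
#' @param base Prime base (2, 3, 5, ...).
#' @param discard Number of initial points to drop before collecting `n`.
#' @param scramble Logical; apply a seeded random permutation of the digits
#'   0..base-1 (the same permutation at every digit position, fixing 0) to
#'   break correlation between high-base dimensions.
#' @param seed Integer seed for the scrambling permutation (required when
#'   `scramble = TRUE`).
#' @return Numeric vector of `n` values in (0, 1).
#' @examples
#' halton_sequence(3, base = 2) # 1/2, 1/4, 3/4
#' @export
halton_sequence <- function(n, base = 2, discard = 0, scramble = FALSE,
                            seed = NULL) {
  n <- check_count(n, "n")
  discard <- check_count(discard, "discard", min = 0L)
  if (!is_prime(base)) {
    abort(sprintf("`base` must be a prime number, got %s.", format(base)))
  }
  perm <- 0:(base - 1)
  if (isTRUE(scramble)) {
    if (is.null(seed)) {
      abort("`seed` is required when `scramble = TRUE`.")
    }
    perm <- withr::with_seed(seed, c(0L, sample(seq_len(base - 1))))
  }
  idx <- discard + seq_len(n)
  h <- numeric(n)
  f <- 1 / base
  while (any(idx > 0)) {
    h <- h + perm[idx %% base + 1L] * f
    idx <- idx %/% base
    f <- f / base
  }
  h
}

#' Standard-normal Halton draw cube
#'
#' Builds the observations x draws x dimensions array of standard-normal
#' values used to approximate the mixing integral of the random-parameters
#' logit.  Dimension d uses the d-th prime as its Halton base; each
#' observation receives its own contiguous, non-overlapping block of
#' `n_draws` points, which are mapped to normals by the inverse CDF.
#' The construction is fully deterministic given its arguments.
#'
#' @param n_obs Number of observations.
#' @param n_draws Draws per observation.
#' @param dims Number of random-coefficient dimensions (at most 25).
#' @param discard Initial Halton points dropped per dimension (default 10).
#' @inheritParams halton_sequence
#' @return A `halton_cube`: numeric array `n_obs x n_draws x dims` with
#'   attributes `bases` and `discard`.
#' @examples
#' cube <- halton_cube(4, 8, dims = 2)
#' dim(cube)
#' @export
halton_cube <- function(n_obs, n_draws, dims = 1, discard = 10,
                        scramble = FALSE, seed = NULL) {
  n_obs <- check_count(n_obs, "n_obs")
  n_draws <- check_count(n_draws, "n_draws")
  dims <- check_count(dims, "dims", min = 0L)
  if (dims > length(HALTON_PRIMES)) {
    abort(sprintf(
      paste0(
        "Requested %d random dimensions but only %d Halton bases are ",
        "configured. Plain Halton degrades in high dimensions; reduce the ",
        "number of random coefficients or extend the prime table."
      ),
      dims, length(HALTON_PRIMES)
    ))
  }
  cube <- array(0, dim = c(n_obs, n_draws, dims))
  bases <- HALTON_PRIMES[seq_len(dims)]
  for (d in seq_len(dims)) {
    u <- halton_sequence(
      n_obs * n_draws, base = bases[d], discard = discard,
      scramble = scramble, seed = if (is.null(seed)) NULL else seed + d
    )
    # column i of the n_draws x n_obs matrix is observation i's block
    cube[, , d] <- t(matrix(qnorm(u), nrow = n_draws, ncol = n_obs))
  }
  structure(cube,
    bases = bases, discard = discard, scramble = isTRUE(scramble),
    class = c("halton_cube", "array")
  )
}

#' @export
print.halton_cube <- function(x, ...) {
  d <- dim(x)
  cat(sprintf(
    "<halton_cube> %d obs x %d draws x %d dim(s); bases: %s; discard: %d%s\n",
    d[1], d[2], d[3], paste(attr(x, "bases"), collapse = ", "),
    attr(x, "discard"), if (isTRUE(attr(x, "scramble"))) "; scrambled" else ""
  ))
  invisible(x)
}
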