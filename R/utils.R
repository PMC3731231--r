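## Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG state
#'
#' Runs `code` with the RNG seeded at `seed`, then restores the caller's RNG
#' state, so seeded operations never perturb the global random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}

## log10 of a weighted sum of 10^x, computed stably.
## x: matrix (rows = cases, cols = grid points) or vector; w: weights summing to 1.
log10_weighted_sum <- function(x, w) {
  if (is.vector(x)) x <- matrix(x, nrow = 1L)
  m <- apply(x, 1L, max)
  m + log10(rowSums(sweep(10^(x - m), 2L, w, `*`)))
}

## Rank-based transform to standard-normal quantiles, ties -> average rank.
## Maps the i-th smallest of n values to qnorm((i - 0.5)/n).
qnorm_transform <- function(x) {
  n <- length(x)
  qnorm((rank(x, ties.method = "average") - 0.5) / n)
}

stopifnot_scalar <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi) {
    stop(sprintf("`%s` must be a single number in [%s, %s]", name, lo, hi),
         call. = FALSE)
  }
  invisible(x)
}
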