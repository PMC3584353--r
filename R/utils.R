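# Internal helpers shared across modules.

# Row maxima of a matrix (C-level, much faster than apply(m, 1, max)).
row_max <- function(m) m[cbind(seq_len(nrow(m)), max.col(m, ties.method = "first"))]

# Numerically stable log(sum(exp(x))) over matrix rows.
log_row_sum_exp <- function(m) {
  mx <- row_max(m)
  mx + log(rowSums(exp(m - mx)))
}

#' Derive a child seed from a base seed and a stream index
#'
#' Deterministic mixing of a master seed with a stream index, kept inside
#' the 32-bit signed integer range that [set.seed()] accepts; used to give
#' every animal, field and analysis stage its own reproducible stream.
#'
#' @param seed master integer seed.
#' @param index stream index (any non-negative integer).
#' @return An integer seed.
#' @examples
#' derive_seed(1, 5)
#' @export
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 7919 + as.double(index) * 104729) %% 2147483647)
}

# Evaluate the one-phase decay curve plateau + (Y0 - plateau) * exp(-k * x).
one_phase_curve <- function(x, Y0, plateau, k) {
  plateau + (Y0 - plateau) * exp(-k * x)
}

stopifnot_scalar <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lo || x > hi) {
    stop(sprintf("'%s' must be a finite scalar in [%s, %s]", name,
                 format(lo), format(hi)), call. = FALSE)
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a fixed RNG seed
#'
#' Runs `expr` with the RNG seeded at `seed` and restores the caller's RNG
#' state afterwards, so seeded generation never perturbs surrounding code.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @examples
#' with_seed(1, rnorm(2))
#' @export
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv())) {
            rm(".Random.seed", envir = globalenv())
          }, add = TRUE)
  set.seed(seed)
  expr
}

# Integer draw, inclusive range given as c(lo, hi).
draw_count <- function(range) {
  if (length(range) == 1L) range <- c(range, range)
  if (range[1L] == range[2L]) return(as.integer(range[1L]))
  as.integer(sample(seq(range[1L], range[2L]), 1L))
}
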