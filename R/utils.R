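# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards.  All exported stochastic functions route their
# randomness through this so no global state leaks.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  expr
}

# Derive a stream of child seeds from one parent seed, kept within 32-bit
# integer range.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Weighted median
#'
#' Median of `x` under nonnegative weights `w`: the smallest `x` at which the
#' cumulative weight reaches half the total.
#'
#' @param x Numeric vector.
#' @param w Nonnegative weights, recycled to `length(x)`.
#' @return A single number.
#' @keywords internal
weighted_median <- function(x, w = rep(1, length(x))) {
  stopifnot(length(x) > 0, all(w >= 0), any(w > 0))
  o <- order(x)
  x <- x[o]
  w <- rep_len(w, length(x))[o]
  cw <- cumsum(w) / sum(w)
  # midpoint convention at an exact 0.5 boundary
  i <- which(cw >= 0.5)[1]
  if (isTRUE(all.equal(cw[i], 0.5)) && i < length(x)) {
    return((x[i] + x[i + 1]) / 2)
  }
  x[i]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not_panel <- function(x) {
  if (!inherits(x, "genotype_panel")) {
    stop("expected a 'genotype_panel' object", call. = FALSE)
  }
  invisible(x)
}
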