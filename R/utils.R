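#' Evaluate an expression under a local random seed
#'
#' Saves and restores the global RNG state so that seeded operations leave no
#' trace in the caller's random stream. All stochastic functions in the
#' package route their randomness through this helper, which makes every
#' output a pure function of its `seed` argument.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
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
  set.seed(seed)
  expr
}

#' Derive a child seed from a parent seed and a stream label
#'
#' Gives independent, reproducible random streams to sub-tasks (one per
#' protein, one per image, ...) without consuming the parent stream.
#' Kept below 2^31 so the result is always a valid R integer seed.
#'
#' @keywords internal
child_seed <- function(seed, ...) {
  parts <- vapply(list(...), function(p) {
    if (is.character(p)) sum(utf8ToInt(p) * seq_along(utf8ToInt(p))) else as.numeric(p)
  }, numeric(1))
  x <- (as.numeric(seed) * 48271 + sum(parts * 7919)) %% 2147483629
  as.integer(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
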