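#' Evaluate an expression with a temporary RNG seed
#'
#' Runs \code{expr} with the random number generator seeded at \code{seed},
#' restoring the caller's RNG state afterwards, so that simulation functions
#' are bit-reproducible without clobbering the session's random stream.
#'
#' @param seed integer seed, or \code{NULL} to leave the RNG untouched.
#' @param expr expression to evaluate.
#' @return the value of \code{expr}.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

#' Derive a per-stage sub-seed from a master seed
#'
#' All randomness in a pipeline run flows from one top-level seed; stages
#' draw from streams derived deterministically from it. Kept below 2^31.
#'
#' @param seed master integer seed.
#' @param k stage offset (small non-negative integer).
#' @return integer sub-seed.
#' @export
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 10000 + k) %% 2147483647)
}

stopifnot_scalar_pos <- function(x, name, strict = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      (strict && x <= 0) || (!strict && x < 0)) {
    stop(sprintf("'%s' must be a %s finite scalar", name,
                 if (strict) "positive" else "non-negative"), call. = FALSE)
  }
  invisible(x)
}
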