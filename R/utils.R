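# Seed plumbing ---------------------------------------------------------

#' Derive a child seed from a master seed
#'
#' All stochastic stages of the package (cohort generation, per-scan
#' noise, splitting, weight initialization, random-vote draws) consume
#' seeds derived from one master seed by a stable counter scheme, so a
#' whole experiment is a pure function of a single integer.
#'
#' @param seed master seed (integer).
#' @param offset non-negative integer counter distinguishing the stream.
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
deriveSeed <- function(seed, offset = 0L) {
  # Lehmer step keeps everything inside 31-bit integer range
  s <- (abs(as.numeric(seed)) %% 2147483646) + 1
  o <- abs(as.numeric(offset)) %% 2147483646
  as.integer(((s * 48271 + o * 16807) %% 2147483647) %% 2147483646 + 1)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's state afterwards.
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Round-half-up (base round() is round-half-even).
roundHalfUp <- function(x) floor(x + 0.5)

`%||%` <- function(a, b) if (is.null(a)) b else a

stopIfNot01 <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1))
    stop(sprintf("'%s' must lie in [0, 1]", name), call. = FALSE)
  invisible(x)
}
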