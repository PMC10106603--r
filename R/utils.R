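# Internal helpers: seeded determinism without disturbing the caller's RNG.

MOD31 <- 2147483647L

#' Derive a child seed from a master seed and integer indices
#'
#' Deterministic fan-out of one master seed into independent child seeds for
#' the pipeline's stochastic stages (one per iteration, stratum, size, ...).
#' A multiplicative congruential mix modulo 2^31 - 1; children of distinct
#' index paths are distinct for all practical purposes.
#'
#' @param master integer master seed.
#' @param ... one or more non-negative integer indices identifying the stage.
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, ...) {
  idx <- c(...)
  stopifnot(length(idx) >= 1, is.finite(master))
  x <- (abs(as.double(master)) %% (MOD31 - 1)) + 1
  for (k in as.double(idx)) {
    x <- (x * 48271 + (k + 1) * 16807) %% MOD31
    if (x == 0) x <- 1
  }
  as.integer(x)
}

# Evaluate `expr` under `seed`, restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
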