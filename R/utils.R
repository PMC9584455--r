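#' @keywords internal
"_PACKAGE"

# Run expr with a temporarily-seeded RNG, restoring the caller's RNG state.
# All exported sampling operations funnel through this so that a given
# (operation, seed) pair is bit-reproducible regardless of surrounding code.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Deterministic sub-seed derivation (Lehmer step); keeps results < 2^31 so
# they are valid R integer seeds. Used to give each repeat/neuron-count its
# own independent, reproducible stream.
derive_seed <- function(seed, index) {
  m <- 2147483647
  s <- (as.double(seed) %% m) + 1
  for (i in seq_len(index)) {
    s <- (48271 * s) %% m
  }
  as.integer(s)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("'%s' must be a positive finite scalar", name), call. = FALSE)
  }
}
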