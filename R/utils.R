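# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's state afterwards so package functions never perturb the
# session RNG.
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

# Deterministic sub-seed derivation: master seed plus a stream index map to
# a value in [1, 2^31 - 2]. Documented splitting rule so the simulators can
# draw independent streams from one master seed.
derive_seed <- function(master, stream) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master))
  ((abs(master) %% 59999) * 30011 + stream * 7919) %% 2147483646 + 1
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) stop(msg, call. = FALSE)
  invisible(TRUE)
}
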