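# Internal helpers shared across modules.

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's stream afterwards. All randomized operations in the package route
# through this so that independent components draw from independent streams.
with_seed <- function(seed, expr) {
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
  set.seed(as.integer(seed))
  expr
}

# Deterministic fan-out of a master seed into per-component sub-seeds.
# Fixed offsets keep components counterfactually comparable: changing, say,
# the treatment model does not perturb the potential-outcome draws.
fanout_seed <- function(seed, offset) {
  (as.integer(seed) + 104729L * as.integer(offset)) %% 2147483629L
}

expit <- function(z) plogis(z)

stop_if_not_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("`%s` must be a single probability in [0, 1]", name),
         call. = FALSE)
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
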