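# Internal helpers shared across modules.

# Deterministic integer seed derivation so that one user-facing seed fans out
# to independent per-stage streams; result always within 32-bit integer range.
seed_child <- function(seed, k) {
  s <- (as.double(seed) %% 97847) * 21401 + as.double(k) * 2063 + 11
  as.integer(s %% 2147483629)
}

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's stream afterwards so simulation never perturbs user code.
with_local_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

stop_validation <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count <- function(x, min = 1L) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x == round(x) && x >= min
}
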