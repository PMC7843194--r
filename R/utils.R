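# internal helpers shared across modules

# Evaluate `expr` with the global RNG seeded to `seed`, restoring the caller's
# RNG state afterwards so library calls never perturb user randomness.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Derive a reproducible child seed from a base seed; stays inside 32-bit range.
child_seed <- function(seed, k) {
  as.integer((as.double(seed) * 1103L + as.double(k) * 12007L) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_param <- function(...) stop(..., call. = FALSE)
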