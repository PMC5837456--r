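# RNG helpers. All stochastic steps (inverse-normal tie breaking, simulation)
# draw from a local RNG stream derived from a user seed, offset per field id,
# so partitioned and whole-cohort runs agree and the caller's RNG state is
# never disturbed.

with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Deterministic per-field seed below 2^31, mixing run seed and field id.
field_seed <- function(seed, field_id) {
  (as.integer(seed) %% 100000L) * 20011L + (as.integer(field_id) %% 20011L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
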