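# Deterministic seeding helpers.  All stochastic operations take an explicit
# seed; the global RNG state is saved and restored around seeded blocks.

.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Derive a reproducible sub-seed (< 2^31) from a master seed and a tag.
.derive_seed <- function(master, tag) {
  h <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
  as.integer((as.numeric(master) * 7919 + h * 104729 + 17) %% 2147483629)
}
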