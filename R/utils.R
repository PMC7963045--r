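# Internal helpers.

# Evaluate expr under set.seed(seed), restoring the caller's RNG state after.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Per-node mode of a label vector with deterministic lexicographic tie-break.
# Returns NA_character_ for empty input.
labelMode <- function(labels) {
  if (!length(labels)) return(NA_character_)
  tab <- table(labels)
  mx <- names(tab)[tab == max(tab)]
  sort(mx)[1L]
}
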