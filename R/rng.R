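# Deterministic seed derivation: every stage of a run draws from a seed
# derived from (master_seed, stage tag, replicate index, ...) so each stage
# is independently reproducible.  Arithmetic stays below 2^53, results in
# [1, 2^31 - 2].
derive_seed <- function(master, ...) {
  tags <- list(...)
  h <- as.numeric(master) %% 2147483647
  for (t in tags) {
    v <- if (is.character(t)) sum(utf8ToInt(t) * seq_along(utf8ToInt(t))) else as.numeric(t)
    h <- (h * 69069 + v + 1) %% 2147483647
    h <- (h * 69069 + 12345) %% 2147483647
  }
  as.integer(h %% 2147483646 + 1)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
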