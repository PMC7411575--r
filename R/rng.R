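#' Derive a deterministic sub-seed
#'
#' All randomized operations in the package take a single integer seed;
#' internal stages (mutation dropping, pairing, missingness, optimizer cycles)
#' each derive their own sub-seed from it with this LCG-style mix, so one seed
#' fully determines a whole pipeline run without any stage sharing draws.
#'
#' @param seed integer master seed.
#' @param index non-negative integer stream index.
#' @return an integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, index) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(index))
  s <- (as.double(seed) %% 2147483647) + 1
  for (i in seq_len(2)) {
    s <- (s * 48271 + as.double(index) * 1103 + 7919) %% 2147483647
  }
  as.integer(s %% 2147483646 + 1)
}

# Evaluate expr with R's RNG seeded at `seed`, restoring the caller's RNG
# state afterwards (the package never clobbers the session RNG).
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
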