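#' Derive a reproducible sub-seed from a master seed and a tag
#'
#' All stochastic steps (initialisation, batching, subsampling, simulation)
#' draw their own seed from one experiment seed via a splitmix-style integer
#' mix, so that changing one step's randomness never perturbs another's.
#'
#' @param seed master integer seed.
#' @param tag character tag naming the consumer (e.g. `"stage1"`, `"batch"`).
#' @return an integer in `[0, 2^31)`.
#' @export
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(tag))
  # accumulate the tag bytes and the seed through a 32-bit LCG-style mix,
  # done in doubles to stay exact (< 2^53)
  m <- 2147483647
  acc <- (abs(seed) %% m)
  for (b in utf8ToInt(tag)) {
    acc <- (acc * 69069 + b * 2654435761 %% m + 1) %% m
  }
  as.integer(acc)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the R RNG to `seed`, evaluates `expr`, and restores the caller's RNG
#' state, so seeded helpers never disturb the global stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}
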