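# Seed plumbing: every stochastic routine takes an explicit seed and derives
# sub-stream seeds deterministically, so one master seed reproduces a whole
# study without global RNG side effects.

#' Derive a sub-stream seed from a master seed
#'
#' Mixes the master seed with one or more integer stream labels through a
#' multiplicative hash, returning a value in `[0, 2^31 - 1)`. Used to hand
#' independent, reproducible seeds to subjects, runs, ROIs and stages.
#'
#' @param seed Integer master seed.
#' @param ... Integer stream labels (e.g. subject index, run index).
#' @return A single integer seed.
#' @export
derive_seed <- function(seed, ...) {
  h <- as.double(seed) %% 2147483647
  for (k in as.double(c(...))) {
    h <- (h * 69069 + k * 40503 + 12345) %% 2147483647
  }
  as.integer(h)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
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
  expr
}
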