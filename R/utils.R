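#' Derive a reproducible sub-stream seed
#'
#' All stochastic components of the package draw from independent seeded
#' sub-streams derived from one master seed, so that adding a generator to a
#' workflow never perturbs the draws of another.  The derivation is a simple
#' deterministic hash of the component name folded into the master seed.
#'
#' @param seed Master integer seed.
#' @param name Character scalar naming the component/sub-stream.
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  codes <- utf8ToInt(name)
  h <- sum(codes * seq_along(codes) * 131)
  as.integer((abs(as.numeric(seed)) * 48271 + h) %% (2^31 - 1))
}

# Evaluate `expr` under a set seed without clobbering the caller's RNG state.
with_substream <- function(seed, name, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(substream_seed(seed, name))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
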