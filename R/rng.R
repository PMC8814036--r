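#' Derive a reproducible sub-stream seed from a master seed and a label
#'
#' All stochastic steps in the package draw their seed from a single master
#' seed through this function, so sub-streams (latent states, noise layers,
#' fold shuffles, weight initialization, ...) are mutually independent and
#' the whole pipeline is reproducible from one integer.
#'
#' The label is hashed with a polynomial rolling hash and combined with the
#' master seed modulo a large prime, keeping the result a valid 32-bit
#' integer seed.
#'
#' @param seed integer master seed.
#' @param label character scalar naming the sub-stream.
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
substream_seed <- function(seed, label) {
  stopifnot(length(seed) == 1L, is.finite(seed), is.character(label),
            length(label) == 1L)
  p <- 2147483587  # large prime < 2^31
  h <- 0
  for (cp in utf8ToInt(label)) h <- (h * 31 + cp) %% p
  s <- (abs(as.numeric(seed)) %% p)
  as.integer(((s * 48271) %% p + h) %% p) + 1L
}

#' Evaluate an expression under a seeded sub-stream, restoring RNG state
#' @noRd
with_substream <- function(seed, label, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(substream_seed(seed, label))
  expr
}
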