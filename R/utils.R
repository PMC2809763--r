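#' Derive a reproducible substream seed
#'
#' Maps a top-level seed and a stream index to a new 32-bit seed via a
#' fixed affine congruential step.  Used so that per-animal simulations are
#' reproducible individually: increasing `n_animals` never reshuffles the
#' streams of earlier animals.
#'
#' @param seed integer top-level seed.
#' @param index non-negative integer stream index.
#' @return an integer seed in `[0, 2147483398]`.
#' @export
derive_seed <- function(seed, index) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed),
            is.numeric(index), all(index >= 0))
  a <- abs(as.double(seed)) %% 2147483647
  # products stay below 2^53, exact in doubles
  as.integer((a * 48271 + as.double(index) * 16807 + 1) %% 2147483399)
}

# run code under a given seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

stop_domain <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}
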