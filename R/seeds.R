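#' Derive a child seed from a root seed and a named substream
#'
#' All randomness in the package flows from one root seed through named
#' substreams (split / forest / evolution / sweep / ...), so that runs are
#' reproducible and substreams do not interfere. The derivation is a simple
#' 31-ary rolling hash over the stream name and index, reduced modulo
#' 2^31 - 1 so the result is always a valid \code{set.seed()} argument.
#'
#' @param seed integer root seed.
#' @param stream character stream name.
#' @param index integer index within the stream (default 0).
#' @return a single integer in [0, 2^31 - 2].
#' @export
childSeed <- function(seed, stream, index = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  m <- 2147483647
  h <- as.double(seed) %% m
  for (code in utf8ToInt(stream)) h <- (h * 31 + code) %% m
  h <- (h * 31 + (as.double(index) %% m)) %% m
  as.integer(h)
}

# Evaluate expr under a local seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
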