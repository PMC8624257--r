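#' Derive a reproducible sub-seed from a master seed and indices
#'
#' Mixes a master seed with any number of small integer indices into a
#' deterministic seed below 2^31, so that every trial, session and repeat
#' of a simulation draws from an independent, reproducible stream.
#'
#' @param ... integers; the first is conventionally a master seed.
#' @return a single integer seed.
#' @export
derive_seed <- function(...) {
  idx <- c(...)
  s <- 0
  for (v in idx) s <- (s * 7919 + (as.numeric(v) %% 2147483563)) %% 2147483563
  as.integer(s) + 1L
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
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

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
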