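# Package-level memoisation for deterministic, pure computations (model
# enumeration, construction, per-problem model predictions). Everything cached
# here is a pure function of its key; stochastic predictions are never cached.

.spatialmm_cache <- new.env(parent = emptyenv())

cache_get <- function(key) {
  if (exists(key, envir = .spatialmm_cache, inherits = FALSE))
    get(key, envir = .spatialmm_cache, inherits = FALSE)
  else NULL
}

cache_set <- function(key, value) {
  assign(key, value, envir = .spatialmm_cache)
  value
}

cached <- function(key, expr) {
  hit <- cache_get(key)
  if (!is.null(hit)) return(hit)
  cache_set(key, force(expr))
}

#' Clear the internal memoisation cache
#'
#' All cached values are pure functions of their inputs, so clearing is never
#' required for correctness; it is occasionally useful when profiling memory.
#'
#' @return Invisibly, the number of entries removed.
#' @export
clear_model_cache <- function() {
  n <- length(ls(.spatialmm_cache, all.names = TRUE))
  rm(list = ls(.spatialmm_cache, all.names = TRUE), envir = .spatialmm_cache)
  invisible(n)
}
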