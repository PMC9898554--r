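# Package-level cache for expensive, deterministic objects (Wigner 3j tensors,
# monomial tables for spherical harmonics, radial-basis normalization stats).
.alc <- new.env(parent = emptyenv())

.cache_get <- function(key, compute) {
  if (!exists(key, envir = .alc, inherits = FALSE)) {
    assign(key, compute(), envir = .alc)
  }
  get(key, envir = .alc, inherits = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
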