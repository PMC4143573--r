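# Internal helpers shared across modules.

# Derive a per-stream seed from one pipeline seed so independent generators
# (growth, expression, qPCR) draw from decoupled streams. Kept below 2^31.
streamSeed <- function(seed, stream) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  codes <- utf8ToInt(stream)
  h <- sum(codes * seq_along(codes))
  as.integer((abs(as.numeric(seed)) * 48271 + h) %% 2147483647)
}

# R^2 of the least-squares line of y on x; 0 for a flat (zero-variance) y.
.linearR2 <- function(x, y) {
  if (stats::sd(y) == 0 || stats::sd(x) == 0) return(0)
  stats::cor(x, y)^2
}

.stopf <- function(...) stop(sprintf(...), call. = FALSE)
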