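# Internal numerical helpers shared across modules.

# Two-sided normal p-value with an underflow floor: extreme test statistics
# report 1e-320 rather than 0 so that -log10(p) stays finite downstream.
P_FLOOR <- 1e-320

pnorm2 <- function(z) {
  p <- 2 * stats::pnorm(-abs(z))
  pmax(p, P_FLOOR)
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log(exp(a) - exp(b)) for a >= b, stable for large magnitudes
logdiffexp <- function(a, b) {
  if (b >= a) return(-Inf)
  a + log1p(-exp(b - a))
}

# chrom:pos matching key used everywhere variants are joined across tables
variant_key <- function(chrom, pos) paste(chrom, pos, sep = ":")

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)
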