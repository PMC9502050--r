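# Independent oracles used across tests. These deliberately avoid the
# package's own code paths: plain-product enumeration for colocalization,
# lm()/closed forms for regression.

# Brute-force colocalization posteriors on a small region: enumerate every
# causal configuration explicitly with ordinary (non-log) arithmetic.
enumerate_coloc <- function(beta1, se1, beta2, se2,
                            p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                            sd1 = 0.15, sd2 = 0.15) {
  abf <- function(b, s, w) {
    r <- w^2 / (s^2 + w^2)
    sqrt(1 - r) * exp((b / s)^2 * r / 2)
  }
  a1 <- abf(beta1, se1, sd1)
  a2 <- abf(beta2, se2, sd2)
  m <- length(a1)
  h0 <- 1
  h1 <- p1 * sum(a1)
  h2 <- p2 * sum(a2)
  h3 <- 0
  for (i in seq_len(m)) for (j in seq_len(m)) {
    if (i != j) h3 <- h3 + p1 * p2 * a1[i] * a2[j]
  }
  h4 <- p12 * sum(a1 * a2)
  h <- c(h0, h1, h2, h3, h4)
  stats::setNames(h / sum(h), paste0("PP", 0:4))
}

# A minimal summary-statistics row for toy tables.
toy_row <- function(snp, pos, beta, se, freq = 0.5, n = 1000,
                    a1 = "A", a2 = "C", chr = "7", info = 1) {
  data.frame(SNP = snp, CHR = chr, POS = pos, A1 = a1, A2 = a2,
             FREQ_A1 = freq, BETA = beta, SE = se,
             P = 2 * pnorm(-abs(beta / se)), N = n, INFO = info,
             stringsAsFactors = FALSE)
}

toy_table <- function(...) do.call(rbind, list(...))
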