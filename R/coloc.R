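#' Wakefield log approximate Bayes factor
#'
#' Evidence for association at a single variant under a normal effect prior:
#' with `V = se^2`, `W = prior_sd^2`, `z = beta/se` and shrinkage
#' `r = W/(V+W)`, the log ABF is `0.5*log(1-r) + z^2*r/2`, oriented so that
#' larger values mean more association. Vectorized over variants.
#'
#' @param beta estimated effect(s).
#' @param se standard error(s), positive.
#' @param prior_sd SD of the effect prior on the trait's scale (default 0.15,
#'   conventional for a quantitative trait in SD units).
#' @return numeric vector of log ABFs.
#' @examples
#' wakefield_abf(0.2, 0.05, 0.2)  # 6.1128
#' @export
wakefield_abf <- function(beta, se, prior_sd = 0.15) {
  if (any(se <= 0)) stopf("se must be positive")
  if (any(prior_sd <= 0)) stopf("prior_sd must be positive")
  V <- se^2
  W <- prior_sd^2
  r <- W / (V + W)
  0.5 * log1p(-r) + (beta / se)^2 * r / 2
}

#' Approximate-Bayes-factor colocalization of two association signals
#'
#' Tests whether two traits' association signals in one region share a single
#' causal variant. Variant panels are intersected by chromosome:position and
#' trait 2 is allele-aligned to trait 1; per-variant Wakefield log ABFs are
#' combined in log space into the five hypothesis posteriors: H0 no
#' association, H1/H2 one trait only, H3 two distinct causal variants
#' (computed stably as the product of single-trait sums minus the shared
#' diagonal), H4 one shared causal variant.
#'
#' @param trait1,trait2 summary-statistics data.frames over the same region.
#' @param p1,p2 per-variant prior probabilities of association with trait 1
#'   and trait 2 (defaults 1e-4).
#' @param p12 per-variant prior probability of association with both
#'   (default 1e-5); must not exceed `min(p1, p2)`.
#' @param prior_sd length-2 effect-prior SDs, one per trait.
#' @param p_filter2 optional p-value cutoff applied to trait 2 before
#'   intersection (mirrors an eQTL input pre-filtered by FDR); `NULL` (the
#'   default) disables it.
#' @return object of class `coloc_result`: `pp` (named PP0..PP4 summing to
#'   1), `labf` (per-variant log ABFs), `n_variants`, `priors`.
#' @export
coloc_abf <- function(trait1, trait2, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                      prior_sd = c(0.15, 0.15), p_filter2 = NULL) {
  if (any(c(p1, p2, p12) <= 0) || any(c(p1, p2, p12) >= 1))
    stopf("priors must be in (0, 1)")
  if (p12 > min(p1, p2)) stopf("p12 must not exceed min(p1, p2)")
  if (length(prior_sd) == 1) prior_sd <- rep(prior_sd, 2)
  if (!is.null(p_filter2))
    trait2 <- trait2[trait2$P < p_filter2, , drop = FALSE]
  t2 <- align_alleles(trait2, trait1)
  key1 <- variant_key(trait1$CHR, trait1$POS)
  key2 <- variant_key(t2$CHR, t2$POS)
  common <- intersect(key1, key2)
  if (length(common) < 2)
    stopf("fewer than 2 shared variants after alignment")
  s1 <- trait1[match(common, key1), ]
  s2 <- t2[match(common, key2), ]

  l1 <- wakefield_abf(s1$BETA, s1$SE, prior_sd[1])
  l2 <- wakefield_abf(s2$BETA, s2$SE, prior_sd[2])
  lsum1 <- logsumexp(l1)
  lsum2 <- logsumexp(l2)
  lsum12 <- logsumexp(l1 + l2)
  lh <- c(H0 = 0,
          H1 = log(p1) + lsum1,
          H2 = log(p2) + lsum2,
          H3 = log(p1) + log(p2) + logdiffexp(lsum1 + lsum2, lsum12),
          H4 = log(p12) + lsum12)
  pp <- exp(lh - logsumexp(lh))
  names(pp) <- paste0("PP", 0:4)
  structure(list(pp = pp,
                 labf = data.frame(SNP = s1$SNP, CHR = s1$CHR, POS = s1$POS,
                                   labf_1 = l1, labf_2 = l2,
                                   stringsAsFactors = FALSE),
                 n_variants = length(common),
                 priors = c(p1 = p1, p2 = p2, p12 = p12)),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("coloc_result over %d variants\n", x$n_variants))
  print(round(x$pp, 4))
  invisible(x)
}

#' Mirrored regional association (Miami) plot for two traits
#'
#' Upper track: -log10(p) of trait 1; lower track (mirrored): trait 2.
#' Dashed lines mark genome-wide significance (5e-8). Base graphics.
#'
#' @param trait1,trait2 summary-statistics data.frames.
#' @param highlight optional snp_id to mark.
#' @param main plot title.
#' @export
plot_miami <- function(trait1, trait2, highlight = NULL, main = "") {
  lp1 <- -log10(trait1$P)
  lp2 <- -log10(trait2$P)
  ylim <- c(-max(lp2, 8), max(lp1, 8))
  graphics::plot(trait1$POS, lp1, pch = 20, col = "firebrick", ylim = ylim,
       xlab = "position (bp)", ylab = "-log10(p)  /  log10(p)", main = main)
  graphics::points(trait2$POS, -lp2, pch = 20, col = "steelblue")
  graphics::abline(h = c(-1, 1) * -log10(5e-8), lty = 2, col = "grey40")
  graphics::abline(h = 0, col = "grey70")
  if (!is.null(highlight)) {
    i <- match(highlight, trait1$SNP)
    j <- match(highlight, trait2$SNP)
    if (!is.na(i)) graphics::points(trait1$POS[i], lp1[i], pch = 18, cex = 1.6)
    if (!is.na(j)) graphics::points(trait2$POS[j], -lp2[j], pch = 18, cex = 1.6)
  }
  invisible(NULL)
}
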