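#' Simulation configuration for the synthetic cohort generator
#'
#' Bundles the parameters of the multi-cohort simulator. Defaults emulate the
#' design of the biomarker GWAS the package targets: four cohorts of sizes
#' 1,210 / 2,954 / 458 / 1,505 (pooled n = 6,127) with a single cis causal
#' variant raising the biomarker by 0.063 phenotype-SD per allele, and a
#' right-skewed biomarker distribution.
#'
#' @param n_per_cohort integer vector of per-cohort sample sizes (all >= 1).
#' @param n_variants number of variants in the regional panel.
#' @param causal_index index (1-based) of the causal variant in the panel.
#' @param causal_freq effect-allele frequency of the causal variant
#'   (default 0.62, the study value); other variants draw from `maf_range`.
#' @param beta_causal per-allele effect on the biomarker, in phenotype-SD.
#' @param maf_range length-2 bounds, strictly inside (0,1), from which
#'   per-variant allele frequencies are drawn uniformly.
#' @param ld_decay correlation half-life in variant-index units: the latent
#'   correlation between variants i and j is `0.5^(|i-j|/ld_decay)`. Must be
#'   positive; values near zero give an effectively independent panel.
#' @param skew log-scale sigma of the shifted log-normal biomarker noise;
#'   0 gives Gaussian noise. See [simulate_biomarker()].
#' @param seed integer seed; identical config + seed gives byte-identical
#'   output from every generator.
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(n_per_cohort = c(100, 100), n_variants = 20,
#'                   causal_index = 10, seed = 7)
#' @export
sim_config <- function(n_per_cohort = c(1210, 2954, 458, 1505),
                       n_variants = 200,
                       causal_index = ceiling(n_variants / 2),
                       causal_freq = 0.62,
                       beta_causal = 0.063,
                       maf_range = c(0.05, 0.5),
                       ld_decay = 10,
                       skew = 0.5,
                       seed = 1L) {
  if (length(n_per_cohort) < 1 || any(n_per_cohort < 1))
    stopf("all cohort sample counts must be >= 1")
  if (n_variants < 1) stopf("n_variants must be >= 1")
  if (length(maf_range) != 2 || any(maf_range <= 0) || any(maf_range >= 1) ||
      maf_range[1] > maf_range[2])
    stopf("maf_range must be ordered bounds strictly inside (0, 1)")
  if (causal_index < 1 || causal_index > n_variants)
    stopf("causal_index %d outside variant panel 1..%d", causal_index, n_variants)
  if (causal_freq <= 0 || causal_freq >= 1)
    stopf("causal_freq must be strictly inside (0, 1)")
  if (ld_decay <= 0) stopf("ld_decay must be positive")
  if (skew < 0) stopf("skew must be >= 0")
  structure(list(n_per_cohort = as.integer(n_per_cohort),
                 n_variants = as.integer(n_variants),
                 causal_index = as.integer(causal_index),
                 causal_freq = causal_freq,
                 beta_causal = beta_causal,
                 maf_range = maf_range,
                 ld_decay = ld_decay,
                 skew = skew,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Variant panel metadata for a simulated region: 1-based positions 1 kb apart
# on chromosome 7, non-palindromic allele pairs so that strand is never
# ambiguous in downstream alignment.
make_panel <- function(m) {
  pairs <- matrix(c("A", "C", "A", "G", "T", "C", "T", "G"), ncol = 2, byrow = TRUE)
  idx <- sample.int(4, m, replace = TRUE)
  data.frame(snp_id = sprintf("var%04d", seq_len(m)),
             chrom = "7",
             pos = 100000000L + 1000L * (seq_len(m) - 1L),
             a1 = pairs[idx, 1],
             a2 = pairs[idx, 2],
             stringsAsFactors = FALSE)
}

#' Simulate cohort genotypes with decaying linkage disequilibrium
#'
#' Draws additive dosages (0/1/2) for all cohorts jointly. Each haplotype is a
#' thresholded latent Gaussian AR(1) process across the variant panel, so that
#' allele-frequency marginals follow Hardy-Weinberg proportions at frequencies
#' sampled uniformly from `maf_range`, while the correlation between variants
#' decays geometrically with index distance (half-life `ld_decay`). Variants
#' that come out monomorphic in the finite sample are redrawn independently so
#' the sample frequency is always strictly inside (0,1).
#'
#' @param config a [sim_config()] object.
#' @return A `genotype_matrix`: list with `dosages` (n x m integer matrix),
#'   `variant_panel` (snp_id, chrom, pos, a1, a2, freq_a1) and `cohort`
#'   (factor of length n assigning samples to cohorts).
#' @export
simulate_genotypes <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  set.seed(config$seed)
  n <- sum(config$n_per_cohort)
  m <- config$n_variants
  panel <- make_panel(m)
  freqs <- stats::runif(m, config$maf_range[1], config$maf_range[2])
  freqs[config$causal_index] <- config$causal_freq
  rho <- 0.5^(1 / config$ld_decay)
  thr <- stats::qnorm(freqs)

  draw_hap <- function() {
    z <- matrix(stats::rnorm(n * m), n, m)
    if (m > 1 && rho > 0) {
      for (j in 2:m) z[, j] <- rho * z[, j - 1] + sqrt(1 - rho^2) * z[, j]
    }
    # allele indicator: latent below the frequency quantile carries the effect allele
    sweep(z, 2, thr, "<") * 1L
  }
  dos <- draw_hap() + draw_hap()

  # finite-sample QC: redraw monomorphic columns (binomial, LD broken for them)
  for (j in seq_len(m)) {
    tries <- 0L
    while ((all(dos[, j] == 0L) || all(dos[, j] == 2L)) && tries < 100L) {
      dos[, j] <- stats::rbinom(n, 2L, freqs[j])
      tries <- tries + 1L
    }
  }
  storage.mode(dos) <- "integer"
  colnames(dos) <- panel$snp_id
  panel$freq_a1 <- freqs
  structure(list(dosages = dos,
                 variant_panel = panel,
                 cohort = factor(rep(seq_along(config$n_per_cohort),
                                     config$n_per_cohort))),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d variants, %d cohort(s)\n",
              nrow(x$dosages), ncol(x$dosages), nlevels(x$cohort)))
  invisible(x)
}

# Skewness of the standardized log-normal noise family, closed form.
lognormal_skewness <- function(sigma) {
  w <- exp(sigma^2)
  (w + 2) * sqrt(w - 1)
}

#' Simulate a skewed quantitative biomarker
#'
#' Phenotype = `beta_causal` x dosage at the causal variant (phenotype-SD per
#' allele) plus right-skewed noise of unit variance. The noise family is a
#' shifted log-normal, `(exp(skew * Z) - mean) / sd` with `Z` standard normal,
#' chosen because its positive support and right tail resemble a serum protein
#' concentration; `skew = 0` degrades to Gaussian noise.
#'
#' @param genotypes a `genotype_matrix` from [simulate_genotypes()].
#' @param config the same [sim_config()] used to generate the genotypes.
#' @return numeric vector of phenotype values, one per sample.
#' @export
simulate_biomarker <- function(genotypes, config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  m <- ncol(genotypes$dosages)
  if (config$causal_index < 1 || config$causal_index > m)
    stopf("causal_index %d outside variant panel 1..%d", config$causal_index, m)
  set.seed(config$seed + 1L)
  n <- nrow(genotypes$dosages)
  s <- config$skew
  z <- stats::rnorm(n)
  if (s > 0) {
    mu <- exp(s^2 / 2)
    sdv <- sqrt((exp(s^2) - 1) * exp(s^2))
    eps <- (exp(s * z) - mu) / sdv
  } else {
    eps <- z
  }
  config$beta_causal * genotypes$dosages[, config$causal_index] + eps
}

# Expected marginal per-allele effects over a panel, given one causal variant:
# beta_j = r_jc * sqrt(v_c / v_j) * beta_causal with v = 2f(1-f). With no LD
# information only the causal variant itself has a nonzero expectation.
marginal_effects <- function(freqs, causal_index, beta_causal, ld = NULL) {
  m <- length(freqs)
  v <- 2 * freqs * (1 - freqs)
  if (is.null(ld)) {
    b <- numeric(m)
    b[causal_index] <- beta_causal
    return(b)
  }
  r <- ld$r[, causal_index]
  r * sqrt(v[causal_index] / v) * beta_causal
}

#' Simulate outcome GWAS summary statistics under an exposure mediation model
#'
#' Generates per-variant log-odds association statistics for a binary outcome
#' whose only genetic pathway runs through the exposure: the expected
#' per-allele log-OR at each variant is `ln(true_causal_or)` times that
#' variant's marginal exposure effect (propagated through LD when an
#' [ld_matrix()] is supplied). Standard errors use the binary-trait
#' approximation `1 / sqrt(2 f (1-f) n_eff)` with
#' `n_eff = 4 / (1/cases + 1/controls)`, and sampling noise is added per seed.
#'
#' @param panel variant panel data.frame with columns `snp_id`, `chrom`,
#'   `pos`, `a1`, `a2`, `freq_a1` (as in `genotype_matrix$variant_panel`).
#' @param true_causal_or causal odds ratio per exposure-SD (> 0).
#' @param causal_index index of the exposure's causal variant in the panel.
#' @param beta_exposure per-allele exposure effect in SD units.
#' @param n_cases,n_controls outcome GWAS case and control counts.
#' @param ld optional [ld_matrix()] over the panel; when supplied, LD-tagged
#'   variants carry proportionally attenuated expected effects.
#' @param seed integer seed.
#' @return A summary-statistics data.frame (SNP, CHR, POS, A1, A2, FREQ_A1,
#'   BETA, SE, P, N, INFO) on the log-odds scale.
#' @export
simulate_outcome_summary <- function(panel, true_causal_or, causal_index,
                                     beta_exposure, n_cases, n_controls,
                                     ld = NULL, seed = 1L) {
  if (true_causal_or <= 0) stopf("true_causal_or must be positive")
  if (n_cases <= 0 || n_controls <= 0)
    stopf("case and control counts must be positive")
  set.seed(as.integer(seed))
  f <- panel$freq_a1
  n_eff <- 4 / (1 / n_cases + 1 / n_controls)
  expected <- log(true_causal_or) *
    marginal_effects(f, causal_index, beta_exposure, ld)
  se <- 1 / sqrt(2 * f * (1 - f) * n_eff)
  beta <- expected + stats::rnorm(length(f)) * se
  sumstats_frame(panel, f, beta, se, n = round(n_cases + n_controls))
}

#' Simulate cis-eQTL summary statistics with a shared or distinct causal variant
#'
#' Generates per-variant association statistics for gene expression in the
#' same region as the biomarker. With `shared_causal = TRUE` the eQTL causal
#' variant is the biomarker causal variant (colocalization H4 ground truth);
#' otherwise `eqtl_causal_index` names a distinct causal variant (H3 truth).
#' `effect_size = 0` gives a pure-noise trait.
#'
#' @inheritParams simulate_outcome_summary
#' @param shared_causal logical; share the biomarker's causal variant?
#' @param effect_size per-allele effect on expression (trait-SD units).
#' @param n eQTL sample size.
#' @param eqtl_causal_index causal variant when `shared_causal` is FALSE.
#' @return A summary-statistics data.frame as in [simulate_outcome_summary()].
#' @export
simulate_eqtl_summary <- function(panel, shared_causal = TRUE, effect_size,
                                  n, causal_index,
                                  eqtl_causal_index = NULL,
                                  ld = NULL, seed = 1L) {
  if (n <= 0) stopf("n must be positive")
  ci <- if (shared_causal) causal_index else eqtl_causal_index
  if (is.null(ci))
    stopf("eqtl_causal_index is required when shared_causal is FALSE")
  set.seed(as.integer(seed))
  f <- panel$freq_a1
  expected <- marginal_effects(f, ci, effect_size, ld)
  se <- 1 / sqrt(2 * f * (1 - f) * n)
  beta <- expected + stats::rnorm(length(f)) * se
  sumstats_frame(panel, f, beta, se, n = n)
}

sumstats_frame <- function(panel, freq, beta, se, n, info = 1) {
  data.frame(SNP = panel$snp_id, CHR = panel$chrom, POS = panel$pos,
             A1 = panel$a1, A2 = panel$a2, FREQ_A1 = freq,
             BETA = beta, SE = se, P = pnorm2(beta / se),
             N = n, INFO = info, stringsAsFactors = FALSE)
}

#' Trial-effect record for rescaling genetic estimates
#'
#' Captures the exposure change induced by an intervention in a clinical
#' trial: the median maximum change in the biomarker from baseline, and the
#' biomarker SD at baseline, both in natural units (IU/L). Defaults are the
#' phase II fixed-dose HIF-PHI trial values (median change 27.1 IU/L over a
#' baseline SD of 61 IU/L, i.e. a 0.44 SD rise).
#'
#' @param median_change median biomarker change from baseline, IU/L.
#' @param baseline_sd biomarker SD at baseline, IU/L (> 0).
#' @export
trial_effect <- function(median_change = 27.1, baseline_sd = 61) {
  if (baseline_sd <= 0) stopf("baseline_sd must be positive")
  structure(list(median_change = median_change, baseline_sd = baseline_sd),
            class = "trial_effect")
}

#' Simulate a null-structured trait matrix for phenome-wide scans
#'
#' Builds a sample-by-trait matrix of independent traits (a configurable
#' fraction binary at 10% prevalence, the rest Gaussian), optionally injecting
#' per-allele dosage effects into named traits. Continuous effects are added
#' on the trait-SD scale; binary effects on the log-odds scale.
#'
#' @param dosage per-sample dosage vector at the scanned variant.
#' @param n_traits number of traits to generate.
#' @param prop_binary fraction of binary traits.
#' @param effects optional named numeric vector: names are trait indices
#'   (as integers), values the per-allele effects to inject.
#' @param seed integer seed.
#' @return list with `traits` (matrix, columns `trait0001`...) and
#'   `trait_type` (character vector, "continuous"/"binary").
#' @export
simulate_traits <- function(dosage, n_traits = 869, prop_binary = 0.2,
                            effects = NULL, seed = 1L) {
  set.seed(as.integer(seed))
  n <- length(dosage)
  type <- ifelse(stats::runif(n_traits) < prop_binary, "binary", "continuous")
  traits <- matrix(NA_real_, n, n_traits,
                   dimnames = list(NULL, sprintf("trait%04d", seq_len(n_traits))))
  eff <- numeric(n_traits)
  if (!is.null(effects)) eff[as.integer(names(effects))] <- effects
  for (j in seq_len(n_traits)) {
    if (type[j] == "binary") {
      pr <- stats::plogis(stats::qlogis(0.1) + eff[j] * dosage)
      traits[, j] <- stats::rbinom(n, 1L, pr)
    } else {
      traits[, j] <- eff[j] * dosage + stats::rnorm(n)
    }
  }
  list(traits = traits, trait_type = type)
}
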