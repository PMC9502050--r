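make_toy_panel <- function() {
  data.frame(snp_id = "v1", chrom = "7", pos = 1L, a1 = "A", a2 = "C",
             freq_a1 = 0.3, stringsAsFactors = FALSE)
}

test_that("generators are pure functions of config and seed", {
  cfg <- sim_config(n_per_cohort = c(120, 80), n_variants = 30,
                    causal_index = 15, seed = 42)
  g1 <- simulate_genotypes(cfg)
  g2 <- simulate_genotypes(cfg)
  expect_identical(g1, g2)
  expect_identical(simulate_biomarker(g1, cfg), simulate_biomarker(g2, cfg))
  o1 <- simulate_outcome_summary(g1$variant_panel, 1.2, 15, 0.063,
                                 5000, 5000, seed = 7)
  o2 <- simulate_outcome_summary(g1$variant_panel, 1.2, 15, 0.063,
                                 5000, 5000, seed = 7)
  expect_identical(o1, o2)
})

test_that("config validation rejects impossible designs", {
  expect_error(sim_config(n_per_cohort = 0), "cohort")
  expect_error(sim_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(sim_config(maf_range = c(0.4, 0.2)), "maf_range")
  expect_error(sim_config(ld_decay = 0), "ld_decay")
  expect_error(sim_config(n_variants = 10, causal_index = 11), "causal_index")
  expect_error(simulate_outcome_summary(make_toy_panel(), 0, 1, 0.1, 10, 10),
               "positive")
  expect_error(simulate_outcome_summary(make_toy_panel(), 1.5, 1, 0.1, 0, 10),
               "positive")
})

test_that("dosages are 0/1/2 and frequencies concentrate at their targets", {
  cfg <- sim_config(n_per_cohort = 50000, n_variants = 1, causal_index = 1,
                    causal_freq = 0.5, maf_range = c(0.5, 0.5), seed = 2)
  g <- simulate_genotypes(cfg)
  expect_true(all(g$dosages %in% 0:2))
  f_hat <- mean(g$dosages) / 2
  # exact binomial 99.9% CI for 2n draws at p = 0.5 is well inside [0.49, 0.51]
  expect_gt(f_hat, 0.49)
  expect_lt(f_hat, 0.51)

  # frequency conservation: dosage mean = 2f within binomial tolerance
  cfg2 <- sim_config(n_per_cohort = 20000, n_variants = 10, causal_index = 5,
                     seed = 11)
  g2 <- simulate_genotypes(cfg2)
  f <- g2$variant_panel$freq_a1
  tol <- 4 * sqrt(f * (1 - f) / (2 * 20000))
  expect_true(all(abs(colMeans(g2$dosages) / 2 - f) < tol))
})

test_that("vanishing ld_decay gives an effectively independent panel", {
  cfg <- sim_config(n_per_cohort = 50000, n_variants = 8, causal_index = 4,
                    causal_freq = 0.3, ld_decay = 1e-9, seed = 2)
  g <- simulate_genotypes(cfg)
  r <- stats::cor(g$dosages)
  diag(r) <- 0
  expect_lt(max(abs(r)), 0.05)
})

test_that("biomarker slope is recoverable and its noise has the stated skew", {
  # null effect: regression slope CI covers 0
  cfg0 <- sim_config(n_per_cohort = 5000, n_variants = 2, causal_index = 1,
                     beta_causal = 0, seed = 31)
  g0 <- simulate_genotypes(cfg0)
  y0 <- simulate_biomarker(g0, cfg0)
  fit0 <- summary(stats::lm(y0 ~ g0$dosages[, 1]))$coefficients
  expect_lt(abs(fit0[2, 1]), 2 * fit0[2, 2])

  # planted 0.063 recovered at n = 100,000 within the analytic SE band
  cfg <- sim_config(n_per_cohort = 1e5, n_variants = 3, causal_index = 2,
                    seed = 4)
  g <- simulate_genotypes(cfg)
  y <- simulate_biomarker(g, cfg)
  slope <- stats::coef(stats::lm(y ~ g$dosages[, 2]))[2]
  expect_gt(slope, 0.053)
  expect_lt(slope, 0.073)

  # moment check: sample skewness near the log-normal closed form
  cfgs <- sim_config(n_per_cohort = 10000, n_variants = 2, causal_index = 1,
                     beta_causal = 0, skew = 0.5, seed = 9)
  gs <- simulate_genotypes(cfgs)
  eps <- simulate_biomarker(gs, cfgs)
  skw <- mean((eps - mean(eps))^3) / stats::sd(eps)^3
  expect_gt(skw, 0)
  expect_lt(abs(skw - targetmr:::lognormal_skewness(0.5)), 0.5)
})

test_that("outcome summary statistics follow the mediation model", {
  panel <- make_toy_panel()
  # null causal OR: mean beta over 500 replicates within 2 SE of its mean
  b0 <- vapply(1:500, function(s)
    simulate_outcome_summary(panel, 1, 1, 0.063, 1000, 1000, seed = s)$BETA,
    numeric(1))
  expect_lt(abs(mean(b0)), 2 * stats::sd(b0) / sqrt(500))

  # OR = 1.5 with exposure effect 0.063: expected log-OR = ln(1.5) * 0.063
  b1 <- vapply(1:500, function(s)
    simulate_outcome_summary(panel, 1.5, 1, 0.063, 50000, 50000,
                             seed = s)$BETA, numeric(1))
  expect_lt(abs(mean(b1) - log(1.5) * 0.063), 2 * stats::sd(b1) / sqrt(500))

  # SE follows the case/control approximation exactly
  o <- simulate_outcome_summary(panel, 1.5, 1, 0.063, 60801, 123504, seed = 1)
  n_eff <- 4 / (1 / 60801 + 1 / 123504)
  expect_equal(o$SE, 1 / sqrt(2 * 0.3 * 0.7 * n_eff))
})

test_that("downstream Wald MR recovers the planted odds ratio", {
  # strongest exposure instrument the study design offers: pooled n = 6,127
  panel <- data.frame(snp_id = "v1", chrom = "7", pos = 1L, a1 = "A",
                      a2 = "C", freq_a1 = 0.62, stringsAsFactors = FALSE)
  truth <- log(1.5)
  hits <- 0
  for (s in 1:200) {
    ex <- simulate_eqtl_summary(panel, TRUE, 0.063, 6127, 1, seed = s)
    out <- simulate_outcome_summary(panel, 1.5, 1, 0.063, 60801, 123504,
                                    seed = 10000 + s)
    w <- wald_ratio(ex$BETA, ex$SE, out$BETA, out$SE,
                    method = "second_order")
    if (w$ci[1] <= truth && w$ci[2] >= truth) hits <- hits + 1
  }
  expect_gte(hits, 0.90 * 200)
})

test_that("null eQTL effect yields no-association posteriors", {
  g <- simulate_genotypes(sim_config(seed = 1))
  ld <- ld_from_genotypes(g)
  t1 <- simulate_eqtl_summary(g$variant_panel, TRUE, 0.063, 6127, 100,
                              ld = ld, seed = 7)
  t2 <- simulate_eqtl_summary(g$variant_panel, TRUE, 0, 861, 100,
                              ld = ld, seed = 8)
  cc <- coloc_abf(t1, t2)
  expect_gt(cc$pp[["PP0"]] + cc$pp[["PP1"]], 0.9)
})

test_that("trial effect record validates its scale", {
  tr <- trial_effect()
  expect_equal(tr$median_change, 27.1)
  expect_equal(tr$baseline_sd, 61)
  expect_error(trial_effect(baseline_sd = 0), "positive")
})
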