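# Fixtures: a small simulated region with known causal structure, plus toy
# orthogonal panels where conditional arithmetic is exact.

sim_region <- function(seed, n = 2000, m = 12, causals = c(6, 9),
                       betas = c(0.2, 0.15), ld_decay = 3) {
  cfg <- sim_config(n_per_cohort = n, n_variants = m, causal_index = causals[1],
                    causal_freq = 0.4, beta_causal = betas[1],
                    maf_range = c(0.2, 0.5), ld_decay = ld_decay, skew = 0,
                    seed = seed)
  g <- simulate_genotypes(cfg)
  set.seed(seed + 5000)
  y <- as.vector(g$dosages[, causals, drop = FALSE] %*% betas) +
    stats::rnorm(n)
  list(g = g, y = y,
       stats = association_scan(g$dosages, y, panel = g$variant_panel),
       ld = ld_from_genotypes(g))
}

orthogonal_toy <- function() {
  tab <- toy_table(toy_row("a", 1, 0.30, 0.03, freq = 0.5, n = 10000),
                   toy_row("b", 2, 0.25, 0.03, freq = 0.5, n = 10000),
                   toy_row("c", 3, 0.01, 0.03, freq = 0.5, n = 10000))
  ld <- ld_matrix(diag(3), c("a", "b", "c"), freqs = rep(0.5, 3),
                  n_ref = 10000)
  list(stats = tab, ld = ld)
}

test_that("conditional statistics equal marginals on an orthogonal panel", {
  toy <- orthogonal_toy()
  cond <- conditional_stats(toy$stats, "a", toy$ld)
  mi <- match(cond$SNP, toy$stats$SNP)
  expect_equal(cond$BETA_C, toy$stats$BETA[mi], tolerance = 1e-10)
  expect_equal(cond$SE_C, toy$stats$SE[mi], tolerance = 1e-10)
  expect_equal(cond$P_C, toy$stats$P[mi], tolerance = 1e-10)
})

test_that("perfect-LD candidates are excluded, never conditioned", {
  r <- matrix(c(1, 1, 0, 1, 1, 0, 0, 0, 1), 3, 3)
  ld <- ld_matrix(r, c("a", "b", "c"), freqs = rep(0.5, 3), n_ref = 1000)
  tab <- toy_table(toy_row("a", 1, 0.3, 0.03), toy_row("b", 2, 0.3, 0.03),
                   toy_row("c", 3, 0.1, 0.03))
  cond <- conditional_stats(tab, "a", ld)
  expect_false("b" %in% cond$SNP)
  expect_true("b" %in% qc_exclusions(cond)$snp_id)
  expect_true("c" %in% cond$SNP)
})

test_that("conditional effects match individual-level residual regression", {
  reg <- sim_region(seed = 55, n = 10000)
  cond <- conditional_stats(reg$stats, "var0006", reg$ld)
  row <- cond[cond$SNP == "var0009", ]
  resid_y <- stats::resid(stats::lm(reg$y ~ reg$g$dosages[, 6]))
  oracle <- stats::coef(stats::lm(resid_y ~ reg$g$dosages[, 9]))[2]
  expect_lt(abs(row$BETA_C - oracle), 2 * row$SE_C)
})

test_that("joint fit reproduces multiple regression under exact LD", {
  reg <- sim_region(seed = 5)
  jf <- joint_fit(reg$stats, c("var0006", "var0009"), reg$ld)
  fit <- stats::lm(reg$y ~ reg$g$dosages[, 6] + reg$g$dosages[, 9])
  truth <- stats::coef(fit)[2:3]
  expect_lt(max(abs(jf$BETA_J - truth) / abs(truth)), 1e-6)

  # singleton and orthogonal-pair identities
  toy <- orthogonal_toy()
  j1 <- joint_fit(toy$stats, "a", toy$ld)
  expect_equal(j1$BETA_J, 0.30, tolerance = 1e-12)
  j2 <- joint_fit(toy$stats, c("a", "b"), toy$ld)
  expect_equal(j2$BETA_J, c(0.30, 0.25), tolerance = 1e-12)
})

test_that("singular selected sets are refused with the offending pair named", {
  r <- matrix(c(1, 1, 1, 1), 2, 2)
  ld <- ld_matrix(r, c("a", "b"), freqs = c(0.5, 0.5), n_ref = 1000)
  tab <- toy_table(toy_row("a", 1, 0.3, 0.03), toy_row("b", 2, 0.3, 0.03))
  expect_error(joint_fit(tab, c("a", "b"), ld), "offending pair [ab] / [ab]")
})

test_that("stepwise selection handles null and single-signal regions", {
  toy <- orthogonal_toy()
  null_stats <- transform(toy$stats, BETA = BETA / 100,
                          P = 2 * stats::pnorm(-abs(BETA / 100 / SE)))
  expect_equal(nrow(stepwise_select(null_stats, toy$ld)$selected), 0)

  # single causal on an orthogonal panel: joint equals marginal
  one <- toy$stats
  one$BETA <- c(0.30, 0.001, -0.002)
  one$P <- 2 * stats::pnorm(-abs(one$BETA / one$SE))
  sel <- stepwise_select(one, toy$ld)
  expect_equal(sel$selected$SNP, "a")
  expect_equal(sel$selected$BETA_J, 0.30, tolerance = 1e-10)
})

test_that("two planted causal variants are recovered across seeds", {
  both <- 0
  bands <- 0
  null_neighbor <- 0
  for (s in 1:20) {
    cfg <- sim_config(n_per_cohort = 10000, n_variants = 60,
                      causal_index = 30, causal_freq = 0.4,
                      beta_causal = 0.15, maf_range = c(0.2, 0.5),
                      ld_decay = 4, skew = 0, seed = 1000 + s)
    g <- simulate_genotypes(cfg)
    set.seed(2000 + s)
    y <- 0.15 * g$dosages[, 30] + 0.12 * g$dosages[, 35] +
      stats::rnorm(nrow(g$dosages))
    ss <- association_scan(g$dosages, y, panel = g$variant_panel)
    sel <- stepwise_select(ss, ld_from_genotypes(g))
    got <- sel$selected$SNP
    if (all(c("var0030", "var0035") %in% got)) {
      both <- both + 1
      j30 <- sel$selected[sel$selected$SNP == "var0030", ]
      j35 <- sel$selected[sel$selected$SNP == "var0035", ]
      if (abs(j30$BETA_J - 0.15) < 2 * j30$SE_J &&
          abs(j35$BETA_J - 0.12) < 2 * j35$SE_J) bands <- bands + 1
    }
    # var0031 sits in strong LD with causal var0030 but carries no effect
    if ("var0031" %in% got) null_neighbor <- null_neighbor + 1
  }
  expect_gte(both, 19)
  expect_gte(bands, 17)   # each 2-SE band covers ~95%; 40 checks total
  expect_equal(null_neighbor, 0)
})

test_that("selection is deterministic and monotone in the threshold", {
  reg <- sim_region(seed = 91, n = 6000)
  sel1 <- stepwise_select(reg$stats, reg$ld)
  shuffled <- reg$stats[rev(seq_len(nrow(reg$stats))), ]
  sel2 <- stepwise_select(shuffled, reg$ld)
  expect_setequal(sel1$selected$SNP, sel2$selected$SNP)

  loose <- stepwise_select(reg$stats, reg$ld, p_threshold = 5e-8)
  tight <- stepwise_select(reg$stats, reg$ld, p_threshold = 5e-10)
  expect_true(all(tight$selected$SNP %in% loose$selected$SNP))
})
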