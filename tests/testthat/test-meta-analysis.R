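test_that("allele alignment flips swapped records and drops the unresolvable", {
  ref <- data.frame(chrom = "7", pos = 1:3,
                    a1 = c("A", "A", "A"), a2 = c("C", "C", "T"),
                    stringsAsFactors = FALSE)
  tab <- toy_table(
    toy_row("ok", 1, 0.063, 0.02, freq = 0.62, a1 = "A", a2 = "C"),
    toy_row("swap", 2, 0.063, 0.02, freq = 0.62, a1 = "C", a2 = "A"),
    toy_row("pal", 3, 0.1, 0.02, freq = 0.50, a1 = "A", a2 = "T"))
  out <- align_alleles(tab, ref)

  expect_equal(out[out$SNP == "ok", c("BETA", "FREQ_A1")],
               data.frame(BETA = 0.063, FREQ_A1 = 0.62),
               ignore_attr = TRUE)
  expect_equal(out[out$SNP == "swap", ]$BETA, -0.063)
  expect_equal(out[out$SNP == "swap", ]$FREQ_A1, 1 - 0.62)
  expect_equal(out[out$SNP == "swap", ]$A1, "A")
  expect_false("pal" %in% out$SNP)
  expect_equal(qc_exclusions(out),
               data.frame(snp_id = "pal", reason = "palindromic"))

  # mismatched allele pair dropped with its own reason
  bad <- align_alleles(toy_row("x", 1, 0.1, 0.02, a1 = "G", a2 = "T"), ref)
  expect_equal(qc_exclusions(bad)$reason, "allele_mismatch")
})

test_that("IVW pooling matches hand arithmetic", {
  # single study: identity
  one <- toy_row("v", 1, 0.063, 0.02)
  m1 <- ivw_meta(list(one))
  expect_equal(m1$BETA, 0.063)
  expect_equal(m1$SE, 0.02)
  expect_equal(m1$N_STUDIES, 1)

  # equal weights: arithmetic mean, SE 1/sqrt(2)
  m2 <- ivw_meta(list(toy_row("v", 1, 1, 1), toy_row("v", 1, 3, 1)))
  expect_equal(m2$BETA, 2)
  expect_equal(round(m2$SE, 4), 0.7071)
  expect_equal(m2$DIRECTION, "++")

  # unequal weights: w = (100, 11.111): beta 0.1000, se 0.09487
  m3 <- ivw_meta(list(toy_row("v", 1, 0, 0.1), toy_row("v", 1, 1, 0.3)))
  expect_equal(round(m3$BETA, 4), 0.1)
  expect_equal(round(m3$SE, 5), 0.09487)
})

test_that("IVW agrees with an independent fixed-effects implementation", {
  skip_if_not_installed("metafor")
  betas <- c(0.05, 0.10, -0.02)
  ses <- c(0.03, 0.05, 0.04)
  m <- ivw_meta(lapply(1:3, function(i) toy_row("v", 1, betas[i], ses[i])))
  fe <- metafor::rma(yi = betas, sei = ses, method = "FE")
  expect_equal(m$BETA, as.numeric(fe$beta), tolerance = 1e-10)
  expect_equal(m$SE, fe$se, tolerance = 1e-10)
  expect_equal(m$Q, as.numeric(fe$QE), tolerance = 1e-10)
})

test_that("IVW is order invariant and self-pooling shrinks SE by sqrt(k)", {
  studies <- list(toy_row("v", 1, 0.1, 0.05), toy_row("v", 1, 0.2, 0.02),
                  toy_row("v", 1, -0.1, 0.08))
  a <- ivw_meta(studies)
  b <- ivw_meta(rev(studies))
  expect_equal(a$BETA, b$BETA)
  expect_equal(a$SE, b$SE)

  one <- toy_row("v", 1, 0.063, 0.02)
  for (k in c(2, 5, 9)) {
    mk <- ivw_meta(rep(list(one), k))
    expect_equal(mk$SE, 0.02 / sqrt(k), tolerance = 1e-12)
    expect_equal(mk$BETA, 0.063, tolerance = 1e-12)
  }
})

test_that("heterogeneity statistic follows chi-square under homogeneity", {
  set.seed(14)
  ses <- c(0.05, 0.08, 0.04, 0.1)
  qs <- replicate(1000, {
    betas <- 0.1 + stats::rnorm(4) * ses
    ivw_meta(lapply(1:4, function(i) toy_row("v", 1, betas[i], ses[i])))$Q
  })
  expect_lt(abs(mean(qs) - 3) / 3, 0.1)
})

test_that("z-score meta pools by sample-size weights", {
  # one study: z unchanged
  z1 <- zscore_meta(list(toy_row("v", 1, 2, 1, n = 500)))
  expect_equal(z1$Z, 2)

  # two equal-n studies at z = 2: pooled 2.828
  z2 <- zscore_meta(list(toy_row("v", 1, 2, 1, n = 500),
                         toy_row("v", 1, 2, 1, n = 500)))
  expect_equal(round(z2$Z, 3), 2.828)

  # opposite signs cancel
  z3 <- zscore_meta(list(toy_row("v", 1, 2, 1, n = 500),
                         toy_row("v", 1, -2, 1, n = 500)))
  expect_equal(z3$Z, 0)
  expect_equal(z3$DIRECTION, "+-")
})

test_that("pooled effect stays within the contributing study range", {
  set.seed(3)
  for (i in 1:20) {
    k <- sample(2:5, 1)
    betas <- stats::rnorm(k)
    ses <- stats::runif(k, 0.01, 0.5)
    m <- ivw_meta(lapply(1:k, function(j) toy_row("v", 1, betas[j], ses[j])))
    expect_gte(m$BETA, min(betas))
    expect_lte(m$BETA, max(betas))
    expect_lte(m$SE, min(ses))
  }
})
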