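#' LD reference matrix for summary-statistics conditional analysis
#'
#' A square allele-aligned correlation matrix over a variant panel, with the
#' reference allele frequencies and reference sample size. `xvar` optionally
#' carries per-variant dosage variances measured in the reference sample;
#' when absent the Hardy-Weinberg value `2 f (1-f)` is used. Supplying the
#' measured variances makes the joint fit exactly reproduce individual-level
#' multiple regression when the LD comes from the same sample as the summary
#' statistics.
#'
#' @param r correlation matrix, entries in \[-1, 1\], symmetric, unit
#'   diagonal, positive semi-definite within 1e-8.
#' @param variant_ids panel identifiers (row/column order of `r`).
#' @param freqs reference effect-allele frequencies.
#' @param n_ref reference sample size.
#' @param xvar optional per-variant dosage variances.
#' @export
ld_matrix <- function(r, variant_ids, freqs, n_ref, xvar = NULL) {
  r <- as.matrix(r)
  m <- length(variant_ids)
  if (!all(dim(r) == m)) stopf("r must be %d x %d", m, m)
  if (max(abs(r - t(r))) > 1e-8) stopf("r must be symmetric")
  if (max(abs(diag(r) - 1)) > 1e-8) stopf("r must have unit diagonal")
  if (min(eigen(r, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
    stopf("r is not positive semi-definite within tolerance")
  if (length(freqs) != m) stopf("freqs length must match panel")
  dimnames(r) <- list(variant_ids, variant_ids)
  structure(list(variant_ids = as.character(variant_ids), r = r,
                 freqs = freqs, n_ref = n_ref, xvar = xvar),
            class = "ld_matrix")
}

#' Compute an LD matrix from simulated genotypes
#'
#' Pearson dosage correlations, in-sample allele frequencies, and measured
#' dosage variances over the panel of a `genotype_matrix`.
#'
#' @param genotypes a `genotype_matrix`.
#' @return an [ld_matrix()].
#' @export
ld_from_genotypes <- function(genotypes) {
  dos <- genotypes$dosages
  ld_matrix(stats::cor(dos),
            variant_ids = genotypes$variant_panel$snp_id,
            freqs = colMeans(dos) / 2,
            n_ref = nrow(dos),
            xvar = apply(dos, 2, stats::var))
}

# Shared geometry for the summary-statistic normal equations. Returns, for a
# set of variant ids, the correlation block (windowed: r set to 0 beyond
# window_bp), the diagonal D = v * n standing in for X'X, and marginal
# effects/SEs/n, all in panel order of `ids`.
cojo_geometry <- function(marginal, ids, ld, window_bp) {
  mi <- match(ids, marginal$SNP)
  li <- match(ids, ld$variant_ids)
  if (anyNA(mi)) stopf("variants missing from summary statistics: %s",
                       paste(ids[is.na(mi)], collapse = ", "))
  if (anyNA(li)) stopf("variants missing from LD panel: %s",
                       paste(ids[is.na(li)], collapse = ", "))
  r <- ld$r[li, li, drop = FALSE]
  pos <- marginal$POS[mi]
  far <- abs(outer(pos, pos, "-")) > window_bp
  r[far] <- 0
  diag(r) <- 1
  f <- ld$freqs[li]
  v <- if (!is.null(ld$xvar)) ld$xvar[li] else 2 * f * (1 - f)
  n <- marginal$N[mi]
  list(r = r, d = v * n, b = marginal$BETA[mi], se = marginal$SE[mi], n = n)
}

#' Joint fit of a selected variant set from summary statistics
#'
#' Solves the multiple-regression normal equations approximated from summary
#' data: with `D = diag(v_j n_j)` standing in for the genotype cross-products
#' and `B = D^(1/2) R D^(1/2)` the off-diagonal surrogate, the joint effects
#' are `solve(B, D %*% beta_marginal)`. The residual variance uses the pooled
#' phenotypic sum of squares of a unit-variance phenotype at the median
#' sample size of the set. When the LD matrix carries variances measured in
#' the same sample as the summary statistics, the joint effects equal
#' individual-level multiple regression exactly.
#'
#' @param marginal summary statistics (e.g. a `meta_result`).
#' @param selected character vector of variant ids to fit jointly.
#' @param ld an [ld_matrix()] covering the variants.
#' @param window_bp distance beyond which LD is treated as zero.
#' @return data.frame: SNP, BETA_J, SE_J, P_J.
#' @export
joint_fit <- function(marginal, selected, ld, window_bp = 1e7) {
  g <- cojo_geometry(marginal, selected, ld, window_bp)
  k <- length(selected)
  B <- sqrt(g$d) * t(sqrt(g$d) * t(g$r))
  if (rcond(B) < 1e-12) {
    rr <- abs(g$r); diag(rr) <- 0
    worst <- which(rr == max(rr), arr.ind = TRUE)[1, ]
    stopf("singular LD submatrix for joint fit; offending pair %s / %s (r = %.3f)",
          selected[worst[1]], selected[worst[2]], g$r[worst[1], worst[2]])
  }
  Binv <- solve(B)
  rhs <- g$d * g$b
  beta <- drop(Binv %*% rhs)
  n_med <- stats::median(g$n)
  yty <- n_med - 1
  sigma2 <- (yty - sum(beta * rhs)) / (n_med - k - 1)
  sigma2 <- max(sigma2, 1e-12)
  se <- sqrt(sigma2 * diag(Binv))
  data.frame(SNP = selected, BETA_J = beta, SE_J = se,
             P_J = pnorm2(beta / se), stringsAsFactors = FALSE)
}

#' Conditional association statistics given a selected variant set
#'
#' For each candidate variant, refits the normal equations on
#' `selected + candidate` and reports the candidate's coefficient: its
#' marginal effect minus the LD projection onto the selected set. The
#' conditional SE uses the candidate's marginal-implied residual variance
#' `D_j se_j^2`, so that on an orthogonal panel conditional and marginal
#' statistics coincide exactly. Candidates whose reference r-squared with any
#' selected variant exceeds `collinearity_r2` are excluded from candidacy and
#' logged (retrievable via [qc_exclusions()]).
#'
#' @inheritParams joint_fit
#' @param collinearity_r2 r-squared cutoff against the selected set.
#' @return data.frame over candidates: SNP, BETA_C, SE_C, P_C; excluded
#'   candidates in the `exclusions` attribute.
#' @export
conditional_stats <- function(marginal, selected, ld,
                              collinearity_r2 = 0.9, window_bp = 1e7) {
  cand <- setdiff(intersect(marginal$SNP, ld$variant_ids), selected)
  if (length(selected) == 0) {
    mi <- match(cand, marginal$SNP)
    out <- data.frame(SNP = cand, BETA_C = marginal$BETA[mi],
                      SE_C = marginal$SE[mi], P_C = marginal$P[mi],
                      stringsAsFactors = FALSE)
    attr(out, "exclusions") <- data.frame(snp_id = character(),
                                          reason = character())
    return(out)
  }
  g_all <- cojo_geometry(marginal, c(selected, cand), ld, window_bp)
  k <- length(selected)
  rows <- vector("list", length(cand))
  excluded <- character(0)
  for (i in seq_along(cand)) {
    r_js <- g_all$r[k + i, seq_len(k)]
    if (any(r_js^2 > collinearity_r2)) {
      excluded <- c(excluded, cand[i])
      next
    }
    sel <- c(seq_len(k), k + i)
    r <- g_all$r[sel, sel, drop = FALSE]
    d <- g_all$d[sel]
    B <- sqrt(d) * t(sqrt(d) * t(r))
    Binv <- tryCatch(solve(B), error = function(e) NULL)
    if (is.null(Binv)) { excluded <- c(excluded, cand[i]); next }
    beta <- drop(Binv %*% (d * g_all$b[sel]))[k + 1]
    sigma2_j <- g_all$d[k + i] * g_all$se[k + i]^2
    se <- sqrt(sigma2_j * Binv[k + 1, k + 1])
    rows[[i]] <- data.frame(SNP = cand[i], BETA_C = beta, SE_C = se,
                            P_C = pnorm2(beta / se), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(SNP = character(), BETA_C = numeric(),
                      SE_C = numeric(), P_C = numeric())
  rownames(out) <- NULL
  attr(out, "exclusions") <- data.frame(
    snp_id = excluded,
    reason = rep("collinear_with_selected", length(excluded)),
    stringsAsFactors = FALSE)
  out
}

#' Stepwise conditional and joint selection of independent signals
#'
#' Forward selection from genome-/region-wide summary statistics: seeded by
#' the smallest marginal p-value below `p_threshold`, then at each step the
#' most significant conditional candidate (given the current set) is added
#' while one remains below threshold. After forward selection stops, the set
#' is jointly refit and variants whose joint p-value rises above threshold
#' are dropped one at a time (backward check). Ties on p are broken by
#' smaller position, making the procedure deterministic.
#'
#' @inheritParams conditional_stats
#' @param p_threshold significance level for selection (default 5e-8).
#' @return object of class `cojo_result`: list with `selected` (data.frame
#'   SNP, BETA_J, SE_J, P_J plus marginal columns), `trace` (one row per
#'   step), `p_threshold`, and `dropped` (backward-eliminated ids).
#' @export
stepwise_select <- function(marginal, ld, p_threshold = 5e-8,
                            collinearity_r2 = 0.9, window_bp = 1e7) {
  if (p_threshold <= 0 || p_threshold >= 1) stopf("p_threshold must be in (0,1)")
  marg <- marginal[marginal$SNP %in% ld$variant_ids, , drop = FALSE]
  empty <- function(trace, dropped = character(0)) {
    structure(list(selected = data.frame(SNP = character(), BETA_J = numeric(),
                                         SE_J = numeric(), P_J = numeric()),
                   trace = trace, p_threshold = p_threshold, dropped = dropped),
              class = "cojo_result")
  }
  trace <- data.frame(step = integer(), snp = character(), p_cond = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(marg) == 0 || min(marg$P) >= p_threshold) return(empty(trace))

  ord <- order(marg$P, marg$POS)
  selected <- marg$SNP[ord[1]]
  trace <- rbind(trace, data.frame(step = 1L, snp = selected,
                                   p_cond = marg$P[ord[1]]))
  repeat {
    cond <- conditional_stats(marg, selected, ld, collinearity_r2, window_bp)
    if (nrow(cond) == 0) break
    pos <- marg$POS[match(cond$SNP, marg$SNP)]
    o <- order(cond$P_C, pos)
    best <- o[1]
    if (cond$P_C[best] >= p_threshold) break
    selected <- c(selected, cond$SNP[best])
    trace <- rbind(trace, data.frame(step = nrow(trace) + 1L,
                                     snp = cond$SNP[best],
                                     p_cond = cond$P_C[best]))
  }
  # backward check on the joint fit
  dropped <- character(0)
  repeat {
    jf <- joint_fit(marg, selected, ld, window_bp)
    if (max(jf$P_J) < p_threshold) break
    worst <- which.max(jf$P_J)
    dropped <- c(dropped, selected[worst])
    selected <- selected[-worst]
    if (length(selected) == 0) return(empty(trace, dropped))
  }
  mi <- match(jf$SNP, marg$SNP)
  sel <- cbind(jf, marg[mi, c("CHR", "POS", "FREQ_A1", "BETA", "SE", "P", "N")])
  rownames(sel) <- NULL
  structure(list(selected = sel, trace = trace, p_threshold = p_threshold,
                 dropped = dropped),
            class = "cojo_result")
}

#' @export
print.cojo_result <- function(x, ...) {
  cat(sprintf("cojo_result: %d independent signal(s) at p < %g\n",
              nrow(x$selected), x$p_threshold))
  if (nrow(x$selected)) print(x$selected[, c("SNP", "BETA_J", "SE_J", "P_J")])
  invisible(x)
}
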