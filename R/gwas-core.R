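#' Rank-based inverse normal transformation
#'
#' Maps a skewed phenotype onto standard-normal quantiles before regression:
#' `qnorm((rank - offset) / (n - 2*offset + 1))`, with average ranks for ties.
#' The default offset is Blom's 3/8. Missing values are transformed within
#' the observed subset and returned as NA in place.
#'
#' @param values numeric phenotype vector with at least 2 distinct values.
#' @param offset rank offset constant in \[0, 0.5\].
#' @return transformed vector, same length and order; mean approximately 0,
#'   variance approximately 1.
#' @examples
#' inverse_normal_transform(c(1, 2, 3))
#' @export
inverse_normal_transform <- function(values, offset = 3 / 8) {
  ok <- !is.na(values)
  x <- values[ok]
  if (length(unique(x)) < 2)
    stopf("inverse normal transform needs >= 2 distinct values")
  n <- length(x)
  r <- rank(x, ties.method = "average")
  out <- values
  out[ok] <- stats::qnorm((r - offset) / (n - 2 * offset + 1))
  out
}

#' Additive association scan of a phenotype on a variant panel
#'
#' Ordinary least squares of the phenotype on each variant's dosage plus
#' covariates (an intercept is always included). Per-variant slope, standard
#' error, and a two-sided p-value from the normal approximation to the
#' t-statistic are returned together with the in-sample allele frequency and
#' n, in the standard summary-statistics layout.
#'
#' Mixed-model relatedness adjustment is deliberately absent: the simulator
#' produces unrelated samples, and all downstream stages consume only summary
#' statistics.
#'
#' @param genotypes a `genotype_matrix`, or a bare dosage matrix plus `panel`.
#' @param phenotype numeric response vector.
#' @param covariates optional numeric covariate matrix (no intercept column).
#' @param panel variant panel, required when `genotypes` is a bare matrix.
#' @return summary-statistics data.frame (SNP, CHR, POS, A1, A2, FREQ_A1,
#'   BETA, SE, P, N, INFO).
#' @export
association_scan <- function(genotypes, phenotype, covariates = NULL,
                             panel = NULL) {
  if (inherits(genotypes, "genotype_matrix")) {
    panel <- genotypes$variant_panel
    dos <- genotypes$dosages
  } else {
    dos <- genotypes
    if (is.null(panel)) stopf("panel is required with a bare dosage matrix")
  }
  n <- nrow(dos)
  if (length(phenotype) != n)
    stopf("phenotype length %d != sample count %d", length(phenotype), n)
  M <- cbind(rep(1, n), covariates)
  if (!is.null(covariates) && nrow(M) != n)
    stopf("covariate rows %d != sample count %d", nrow(covariates), n)
  qrM <- qr(M)
  if (qrM$rank < ncol(M))
    stopf("covariate design is rank deficient (rank %d of %d columns)",
          qrM$rank, ncol(M))
  ry <- qr.resid(qrM, phenotype)
  rx <- qr.resid(qrM, dos)
  sxx <- colSums(rx^2)
  if (any(sxx <= 0))
    stopf("monomorphic dosage column(s) after covariate projection: %s",
          paste(panel$snp_id[sxx <= 0], collapse = ", "))
  sxy <- colSums(rx * ry)
  beta <- sxy / sxx
  df <- n - ncol(M) - 1
  rss <- sum(ry^2) - beta * sxy
  se <- sqrt(pmax(rss, 0) / df / sxx)
  freq <- colMeans(dos) / 2
  sumstats_frame(panel, freq, beta, se, n = n)
}

#' QC thresholds for summary-statistics filtering
#'
#' @param mac_min minimum minor allele count; filter keeps MAC strictly
#'   greater than this (default 3).
#' @param info_min minimum imputation quality, in \[0,1\] (default 0.3).
#' @param eaf_bounds open interval of plausible effect-allele frequencies;
#'   the default (0,1) excludes monomorphic or impossible frequencies.
#' @param maf_min post-meta-analysis minor allele frequency floor; variants
#'   with MAF below it are excluded (default 0.01).
#' @export
qc_thresholds <- function(mac_min = 3, info_min = 0.3,
                          eaf_bounds = c(0, 1), maf_min = 0.01) {
  if (mac_min < 0) stopf("mac_min must be >= 0")
  if (info_min < 0 || info_min > 1) stopf("info_min must be in [0, 1]")
  structure(list(mac_min = mac_min, info_min = info_min,
                 eaf_bounds = eaf_bounds, maf_min = maf_min),
            class = "qc_thresholds")
}

#' Filter summary statistics with an exclusion log
#'
#' `stage = "pre_meta"` applies the per-study filters (minor allele count
#' strictly above `mac_min`, imputation Info at least `info_min`, effect
#' allele frequency strictly inside `eaf_bounds`); `stage = "post_meta"`
#' applies the minor allele frequency floor `maf_min`. Surviving rows keep
#' their input order; every excluded row is logged with a reason, retrievable
#' via [qc_exclusions()]. The operation is idempotent.
#'
#' @param stats summary-statistics data.frame.
#' @param thresholds a [qc_thresholds()] object.
#' @param stage which filter set to apply.
#' @return filtered data.frame with an `exclusions` attribute
#'   (data.frame: snp_id, reason).
#' @export
qc_filter <- function(stats, thresholds = qc_thresholds(),
                      stage = c("pre_meta", "post_meta")) {
  stage <- match.arg(stage)
  if (nrow(stats) == 0) stopf("empty summary statistics")
  f <- stats$FREQ_A1
  maf <- pmin(f, 1 - f)
  drop_reason <- rep(NA_character_, nrow(stats))
  if (stage == "pre_meta") {
    mac <- 2 * stats$N * maf
    drop_reason[mac <= thresholds$mac_min] <- "MAC"
    drop_reason[is.na(drop_reason) & stats$INFO < thresholds$info_min] <- "INFO"
    bad_eaf <- f <= thresholds$eaf_bounds[1] | f >= thresholds$eaf_bounds[2]
    drop_reason[is.na(drop_reason) & bad_eaf] <- "EAF"
  } else {
    drop_reason[maf < thresholds$maf_min] <- "MAF"
  }
  keep <- is.na(drop_reason)
  out <- stats[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "exclusions") <- data.frame(
    snp_id = stats$SNP[!keep],
    reason = drop_reason[!keep],
    stringsAsFactors = FALSE)
  out
}

#' Retrieve the exclusion log attached by a filtering step
#' @param x output of [qc_filter()] or [align_alleles()].
#' @export
qc_exclusions <- function(x) {
  attr(x, "exclusions") %||%
    data.frame(snp_id = character(), reason = character())
}
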