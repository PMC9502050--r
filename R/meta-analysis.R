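#' Align summary statistics to a reference allele orientation
#'
#' Matches variants to the reference by chromosome:position (snp_id as
#' tiebreaker when several variants share a position) and harmonizes the
#' effect allele: records whose alleles are swapped relative to the reference
#' have their beta negated and frequency flipped; records whose allele pair
#' does not match the reference are dropped and logged. Palindromic variants
#' (A/T or C/G) with minor-allele frequency above `palindromic_maf` cannot be
#' strand-resolved from summary data and are dropped by default.
#'
#' @param stats summary-statistics data.frame.
#' @param reference data.frame with columns `chrom`/`CHR`, `pos`/`POS`,
#'   `a1`/`A1`, `a2`/`A2` giving the target orientation.
#' @param palindromic_maf MAF above which palindromic variants are dropped.
#' @return aligned data.frame; dropped rows logged in the `exclusions`
#'   attribute (see [qc_exclusions()]).
#' @export
align_alleles <- function(stats, reference, palindromic_maf = 0.42) {
  ref <- normalize_ref(reference)
  key_s <- variant_key(stats$CHR, stats$POS)
  key_r <- variant_key(ref$chrom, ref$pos)
  idx <- match(key_s, key_r)
  reason <- rep(NA_character_, nrow(stats))
  reason[is.na(idx)] <- "not_in_reference"

  a1 <- toupper(stats$A1); a2 <- toupper(stats$A2)
  pal <- paste(pmin(a1, a2), pmax(a1, a2)) %in% c("A T", "C G")
  maf <- pmin(stats$FREQ_A1, 1 - stats$FREQ_A1)
  reason[is.na(reason) & pal & maf > palindromic_maf] <- "palindromic"

  out <- stats
  ok <- which(is.na(reason))
  for (i in ok) {
    ra1 <- ref$a1[idx[i]]; ra2 <- ref$a2[idx[i]]
    if (a1[i] == ra1 && a2[i] == ra2) {
      # already aligned
    } else if (a1[i] == ra2 && a2[i] == ra1) {
      out$BETA[i] <- -out$BETA[i]
      out$FREQ_A1[i] <- 1 - out$FREQ_A1[i]
      out$A1[i] <- ra1
      out$A2[i] <- ra2
    } else {
      reason[i] <- "allele_mismatch"
    }
  }
  keep <- is.na(reason)
  res <- out[keep, , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "exclusions") <- data.frame(snp_id = stats$SNP[!keep],
                                        reason = reason[!keep],
                                        stringsAsFactors = FALSE)
  res
}

normalize_ref <- function(reference) {
  nm <- names(reference)
  pick <- function(a, b) reference[[if (a %in% nm) a else b]]
  data.frame(chrom = as.character(pick("chrom", "CHR")),
             pos = pick("pos", "POS"),
             a1 = toupper(pick("a1", "A1")),
             a2 = toupper(pick("a2", "A2")),
             stringsAsFactors = FALSE)
}

#' Inverse-variance-weighted fixed-effects meta-analysis
#'
#' METAL-style pooling of allele-aligned per-study summary statistics. For
#' each variant the study weights are `w = 1/se^2`; the pooled effect is
#' `sum(w * beta) / sum(w)` with standard error `1/sqrt(sum(w))`, a two-sided
#' normal p-value, Cochran's Q heterogeneity statistic, and a METAL-style
#' per-study direction string ("+", "-", "0" for zero effect, "?" for a study
#' not contributing the variant). Variants present in a single study are
#' retained (n_studies records how many contributed).
#'
#' @param studies list of aligned summary-statistics data.frames.
#' @return data.frame of class `meta_result`: SNP, CHR, POS, A1, A2, FREQ_A1
#'   (sample-size-weighted), BETA, SE, P, N, INFO, Q, N_STUDIES, DIRECTION.
#' @examples
#' s <- data.frame(SNP = "v1", CHR = "7", POS = 1L, A1 = "A", A2 = "C",
#'                 FREQ_A1 = 0.5, BETA = 1, SE = 1, P = 0.3, N = 100, INFO = 1)
#' ivw_meta(list(s, transform(s, BETA = 3)))
#' @export
ivw_meta <- function(studies) {
  studies <- as_study_list(studies)
  keys <- lapply(studies, function(s) variant_key(s$CHR, s$POS))
  all_keys <- unique(unlist(keys))
  k <- length(studies)
  rows <- lapply(all_keys, function(key) {
    direction <- character(k)
    w_sum <- wb_sum <- q_acc <- n_tot <- fn_sum <- info_min <- NULL
    betas <- ses <- ns <- fs <- infos <- numeric(0)
    proto <- NULL
    for (i in seq_len(k)) {
      j <- match(key, keys[[i]])
      if (is.na(j)) { direction[i] <- "?"; next }
      s <- studies[[i]][j, ]
      if (is.null(proto)) proto <- s
      betas <- c(betas, s$BETA); ses <- c(ses, s$SE)
      ns <- c(ns, s$N); fs <- c(fs, s$FREQ_A1); infos <- c(infos, s$INFO)
      direction[i] <- if (s$BETA > 0) "+" else if (s$BETA < 0) "-" else "0"
    }
    if (any(ses <= 0)) stopf("non-positive SE at %s", key)
    w <- 1 / ses^2
    bm <- sum(w * betas) / sum(w)
    sem <- 1 / sqrt(sum(w))
    data.frame(SNP = proto$SNP, CHR = proto$CHR, POS = proto$POS,
               A1 = proto$A1, A2 = proto$A2,
               FREQ_A1 = sum(ns * fs) / sum(ns),
               BETA = bm, SE = sem, P = pnorm2(bm / sem),
               N = sum(ns), INFO = min(infos),
               Q = sum(w * (betas - bm)^2),
               N_STUDIES = length(betas),
               DIRECTION = paste(direction, collapse = ""),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$CHR, out$POS), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("meta_result", "data.frame")
  out
}

#' Sample-size-weighted z-score meta-analysis
#'
#' Pools aligned studies on the z scale: `z_meta = sum(z_i * sqrt(n_i)) /
#' sqrt(sum(n_i))` (alignment signs already applied by [align_alleles()]),
#' with a two-sided normal p-value. Suited to inputs reported as
#' t/z-statistics without a common effect scale, such as expression QTL
#' meta-analyses. Variants lacking a sample size in any contributing study
#' are omitted.
#'
#' @param studies list of aligned summary-statistics data.frames.
#' @return data.frame: SNP, CHR, POS, A1, A2, Z, P, N, N_STUDIES, DIRECTION.
#' @export
zscore_meta <- function(studies) {
  studies <- as_study_list(studies)
  keys <- lapply(studies, function(s) variant_key(s$CHR, s$POS))
  all_keys <- unique(unlist(keys))
  k <- length(studies)
  rows <- lapply(all_keys, function(key) {
    zs <- ns <- numeric(0)
    direction <- character(k)
    proto <- NULL
    drop <- FALSE
    for (i in seq_len(k)) {
      j <- match(key, keys[[i]])
      if (is.na(j)) { direction[i] <- "?"; next }
      s <- studies[[i]][j, ]
      if (is.na(s$N)) drop <- TRUE
      if (is.null(proto)) proto <- s
      z <- s$BETA / s$SE
      zs <- c(zs, z); ns <- c(ns, s$N)
      direction[i] <- if (z > 0) "+" else if (z < 0) "-" else "0"
    }
    if (drop) return(NULL)
    zm <- sum(zs * sqrt(ns)) / sqrt(sum(ns))
    data.frame(SNP = proto$SNP, CHR = proto$CHR, POS = proto$POS,
               A1 = proto$A1, A2 = proto$A2,
               Z = zm, P = pnorm2(zm), N = sum(ns),
               N_STUDIES = length(zs),
               DIRECTION = paste(direction, collapse = ""),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$CHR, out$POS), , drop = FALSE]
  rownames(out) <- NULL
  out
}

as_study_list <- function(studies) {
  if (is.data.frame(studies)) studies <- list(studies)
  if (length(studies) < 1) stopf("at least one study is required")
  studies
}
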