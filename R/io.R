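# Tab-separated summary-statistics I/O and the other text formats the
# pipeline exchanges. Coordinates are 1-based; intervals closed.

SUMSTATS_COLUMNS <- c("SNP", "CHR", "POS", "A1", "A2", "FREQ_A1",
                      "BETA", "SE", "P", "N", "INFO")

#' Read GWAS summary statistics from a TSV file
#'
#' Expects a header with the columns SNP, CHR, POS, A1, A2, FREQ_A1, BETA,
#' SE, P, N, INFO (extra columns pass through). Alleles are uppercased.
#' Rows violating the record invariants (SE > 0, frequency strictly inside
#' (0,1), p in (0,1], identical alleles) are rejected and logged with their
#' file line numbers in the `rejected` attribute.
#'
#' @param path file path.
#' @return summary-statistics data.frame; rejected rows in
#'   `attr(, "rejected")` (line, snp_id, reason).
#' @export
read_sumstats <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(SUMSTATS_COLUMNS, names(x))
  if (length(missing))
    stopf("missing mandatory column(s): %s", paste(missing, collapse = ", "))
  x$A1 <- toupper(x$A1)
  x$A2 <- toupper(x$A2)
  x$CHR <- as.character(x$CHR)
  reason <- rep(NA_character_, nrow(x))
  reason[!is.finite(x$SE) | x$SE <= 0] <- "nonpositive_SE"
  bad_f <- !is.finite(x$FREQ_A1) | x$FREQ_A1 <= 0 | x$FREQ_A1 >= 1
  reason[is.na(reason) & bad_f] <- "frequency_out_of_range"
  reason[is.na(reason) & (!is.finite(x$P) | x$P <= 0 | x$P > 1)] <- "invalid_p"
  reason[is.na(reason) & x$A1 == x$A2] <- "identical_alleles"
  keep <- is.na(reason)
  out <- x[keep, , drop = FALSE]
  rownames(out) <- NULL
  # +1 for the header: reported numbers are physical file lines
  attr(out, "rejected") <- data.frame(line = which(!keep) + 1L,
                                      snp_id = x$SNP[!keep],
                                      reason = reason[!keep],
                                      stringsAsFactors = FALSE)
  out
}

#' Write summary statistics as TSV
#' @param stats summary-statistics data.frame.
#' @param path output path.
#' @export
write_sumstats <- function(stats, path) {
  utils::write.table(stats, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read/write an LD correlation matrix as whitespace-delimited square text
#'
#' The format is a header row of variant ids followed by the square matrix.
#' Frequencies and reference sample size are not part of the file and must
#' be supplied on read.
#'
#' @param path file path.
#' @param freqs reference allele frequencies (read only).
#' @param n_ref reference sample size (read only).
#' @return [read_ld_matrix()] returns an [ld_matrix()].
#' @export
read_ld_matrix <- function(path, freqs, n_ref) {
  ids <- scan(path, what = character(), nlines = 1, quiet = TRUE)
  r <- as.matrix(utils::read.table(path, skip = 1))
  ld_matrix(r, ids, freqs, n_ref)
}

#' @rdname read_ld_matrix
#' @param ld an [ld_matrix()] (write only).
#' @export
write_ld_matrix <- function(ld, path) {
  writeLines(paste(ld$variant_ids, collapse = " "), path)
  utils::write.table(format(ld$r, digits = 10), path, append = TRUE,
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' Collects every stage's parameters plus stage toggles into one list that
#' round-trips through YAML unchanged. Defaults reproduce the demonstration
#' study: four cohorts (pooled n = 6,127), causal effect 0.063 SD/allele,
#' shared-causal eQTL at n = 861, CAD-scale binary outcome, and the
#' trial-effect record (27.1 / 61 IU/L).
#'
#' @param sim arguments for [sim_config()].
#' @param qc arguments for [qc_thresholds()].
#' @param gwas list: `transform`, the per-cohort phenotype transformation
#'   before the scan: `"int"` (inverse normal, the study procedure for a
#'   skewed biomarker) or `"none"` (regress the raw phenotype; under the
#'   generator's additive noise model this scale carries the planted
#'   per-allele effect — see the methods vignette).
#' @param cojo list: p_threshold, collinearity_r2, window_bp.
#' @param coloc list: p1, p2, p12, prior_sd, eqtl_effect, eqtl_n,
#'   shared_causal.
#' @param mr list: true_causal_or, n_cases, n_controls, method.
#' @param trial list: median_change, baseline_sd.
#' @param units list: sd_in_natural_units.
#' @param phewas list: n_traits, prop_binary, threshold.
#' @param stages character vector of stages to run, in dependency order from
#'   `"simulate"` through `"phewas"`.
#' @export
pipeline_config <- function(sim = list(),
                            qc = list(),
                            gwas = list(transform = "int"),
                            cojo = list(p_threshold = 5e-8,
                                        collinearity_r2 = 0.9,
                                        window_bp = 1e7),
                            coloc = list(p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                                         prior_sd = c(0.15, 0.15),
                                         eqtl_effect = 0.3, eqtl_n = 861,
                                         shared_causal = TRUE),
                            mr = list(true_causal_or = 1.0,
                                      n_cases = 60801, n_controls = 123504,
                                      method = "first_order"),
                            trial = list(median_change = 27.1,
                                         baseline_sd = 61),
                            units = list(sd_in_natural_units = 5.1),
                            phewas = list(n_traits = 100, prop_binary = 0.2,
                                          threshold = 5e-8),
                            stages = c("simulate", "gwas", "meta", "cojo",
                                       "coloc", "mr", "phewas")) {
  structure(list(sim = sim, qc = qc, gwas = gwas, cojo = cojo,
                 coloc = coloc, mr = mr,
                 trial = trial, units = units, phewas = phewas,
                 stages = stages),
            class = "pipeline_config")
}

#' Read or write a pipeline configuration as YAML
#' @param path file path.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' @rdname read_pipeline_config
#' @param config a [pipeline_config()].
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
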