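#' Run the full analysis chain on synthetic cohorts
#'
#' Executes the enabled stages in dependency order: simulate cohorts,
#' per-cohort GWAS (inverse normal transform + additive scan + pre-meta QC),
#' inverse-variance meta-analysis with post-meta MAF filtering, stepwise
#' conditional/joint signal selection, colocalization against a simulated
#' cis-eQTL, Wald-ratio Mendelian randomization of a simulated binary outcome
#' with trial-effect rescaling, and a phenome-wide scan of the causal
#' variant. Every source of randomness derives from the simulation seed, so
#' a rerun with the same configuration writes byte-identical outputs. When
#' `out_dir` is given, each stage writes its table plus a provenance record
#' (stage, parameters, seed, package version).
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory (created if missing).
#' @return invisibly, a named list with the per-stage results.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stages <- config$stages
  need <- function(dep, stage) {
    if (!dep %in% stages)
      stopf("stage '%s' requires stage '%s', which is not enabled", stage, dep)
  }
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  provenance <- list()
  note <- function(stage, params) {
    provenance[[stage]] <<- list(stage = stage, params = params,
                                 seed = scfg$seed,
                                 version = as.character(
                                   utils::packageVersion("targetmr")))
  }
  res <- list()
  scfg <- do.call(sim_config, config$sim)
  thr <- do.call(qc_thresholds, config$qc)

  if ("simulate" %in% stages) {
    geno <- simulate_genotypes(scfg)
    pheno <- simulate_biomarker(geno, scfg)
    res$genotypes <- geno
    res$phenotype <- pheno
    note("simulate", unclass(scfg))
  }

  if ("gwas" %in% stages) {
    need("simulate", "gwas")
    transform <- config$gwas$transform %||% "int"
    res$cohort_stats <- lapply(levels(geno$cohort), function(ch) {
      idx <- geno$cohort == ch
      y <- pheno[idx]
      if (transform == "int") y <- inverse_normal_transform(y)
      s <- association_scan(geno$dosages[idx, , drop = FALSE], y,
                           panel = geno$variant_panel)
      qc_filter(s, thr, "pre_meta")
    })
    note("gwas", c(unclass(thr), transform = transform))
  }

  if ("meta" %in% stages) {
    need("gwas", "meta")
    aligned <- lapply(res$cohort_stats, align_alleles,
                      reference = geno$variant_panel)
    meta <- ivw_meta(aligned)
    meta <- qc_filter(meta, thr, "post_meta")
    res$meta <- meta
    if (!is.null(out_dir)) write_sumstats(meta, file.path(out_dir, "meta.tsv"))
    note("meta", list(scheme = "ivw"))
  }

  if ("cojo" %in% stages) {
    need("meta", "cojo")
    ld <- ld_from_genotypes(geno)
    res$ld <- ld
    res$cojo <- stepwise_select(res$meta, ld,
                                p_threshold = config$cojo$p_threshold,
                                collinearity_r2 = config$cojo$collinearity_r2,
                                window_bp = config$cojo$window_bp)
    if (!is.null(out_dir))
      utils::write.table(res$cojo$selected, file.path(out_dir, "cojo.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    note("cojo", config$cojo)
  }

  if ("coloc" %in% stages) {
    need("meta", "coloc")
    ld <- res$ld %||% ld_from_genotypes(geno)
    cc <- config$coloc
    eqtl <- simulate_eqtl_summary(geno$variant_panel,
                                  shared_causal = cc$shared_causal,
                                  effect_size = cc$eqtl_effect,
                                  n = cc$eqtl_n,
                                  causal_index = scfg$causal_index,
                                  eqtl_causal_index = cc$eqtl_causal_index,
                                  ld = ld, seed = scfg$seed + 2L)
    res$eqtl <- eqtl
    res$coloc <- coloc_abf(res$meta, eqtl, p1 = cc$p1, p2 = cc$p2,
                           p12 = cc$p12, prior_sd = cc$prior_sd)
    if (!is.null(out_dir))
      utils::write.table(
        data.frame(hypothesis = names(res$coloc$pp), pp = res$coloc$pp),
        file.path(out_dir, "coloc.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
    note("coloc", cc[c("p1", "p2", "p12", "shared_causal")])
  }

  if ("mr" %in% stages) {
    need("meta", "mr")
    mc <- config$mr
    instrument <- geno$variant_panel$snp_id[scfg$causal_index]
    exp_row <- res$meta[res$meta$SNP == instrument, ]
    if (nrow(exp_row) != 1)
      stopf("instrument %s absent from meta-analysis output", instrument)
    outcome <- simulate_outcome_summary(geno$variant_panel,
                                        true_causal_or = mc$true_causal_or,
                                        causal_index = scfg$causal_index,
                                        beta_exposure = scfg$beta_causal,
                                        n_cases = mc$n_cases,
                                        n_controls = mc$n_controls,
                                        ld = res$ld %||% NULL,
                                        seed = scfg$seed + 3L)
    out_row <- outcome[outcome$SNP == instrument, ]
    wald <- wald_ratio(exp_row$BETA, exp_row$SE, out_row$BETA, out_row$SE,
                       method = mc$method, instrument = instrument)
    tr <- trial_effect(config$trial$median_change, config$trial$baseline_sd)
    sf <- scaling_factor(tr, exp_row$BETA)
    res$outcome <- outcome
    res$mr <- list(wald = wald,
                   scaling = sf,
                   rescaled = rescale_effect(wald, sf$scaling_sd),
                   natural_units = convert_units(
                     exp_row$BETA, do.call(unit_map, config$units)))
    if (!is.null(out_dir)) {
      w <- res$mr$wald; rs <- res$mr$rescaled
      utils::write.table(
        data.frame(instrument = instrument,
                   ratio = w$ratio, se = w$se,
                   ci_low = w$ci[1], ci_high = w$ci[2], p = w$p,
                   or = w$or_scale$or,
                   scaling_sd = sf$scaling_sd, factor = sf$factor,
                   rescaled_or = rs$or_scale$or,
                   exclusion_bound = rs$exclusion_bound),
        file.path(out_dir, "mr.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
    }
    note("mr", mc)
  }

  if ("phewas" %in% stages) {
    need("simulate", "phewas")
    pc <- config$phewas
    dos <- geno$dosages[, scfg$causal_index]
    tm <- simulate_traits(dos, n_traits = pc$n_traits,
                          prop_binary = pc$prop_binary,
                          seed = scfg$seed + 4L)
    res$phewas <- phewas_scan(dos, tm$traits, tm$trait_type,
                              threshold = pc$threshold)
    if (!is.null(out_dir))
      utils::write.table(res$phewas, file.path(out_dir, "phewas.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    note("phewas", pc)
  }

  if (!is.null(out_dir))
    yaml::write_yaml(provenance, file.path(out_dir, "provenance.yaml"))
  invisible(res)
}
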