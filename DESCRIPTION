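Package: targetmr
Title: Drug-Target Mendelian Randomization from GWAS Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of the statistical-genetics chain used
    in drug-target Mendelian randomization of a circulating biomarker:
    per-cohort inverse-normal transformation and additive association scans,
    METAL-style inverse-variance-weighted fixed-effects meta-analysis with
    allele alignment and QC filtering, GCTA-COJO-style stepwise conditional
    and joint signal selection from summary statistics plus an LD reference,
    Wakefield approximate-Bayes-factor colocalization of a protein GWAS with
    a cis-eQTL, single-instrument Wald-ratio Mendelian randomization with
    delta-method standard errors, rescaling of genetic effect estimates to a
    clinical-trial-induced exposure change, and a single-variant phenome-wide
    scan. A synthetic multi-cohort data generator with controllable linkage
    disequilibrium, skewed biomarker noise and shared/distinct causal
    variants makes every stage testable without access to cohort data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    metafor,
    jsonlite
Config/testthat/edition: 3
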