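---
title: "Methods: drug-target Mendelian randomization from summary statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: drug-target Mendelian randomization from summary statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Can a drug that raises a circulating protein be expected to change disease
risk? When a *cis* variant near the protein's gene shifts its circulating
level, allele assortment at that variant is a natural randomized experiment:
carriers experience a small, lifelong difference in exposure. `targetmr`
implements the full statistical chain used to exploit this design for a
biomarker such as erythropoietin (EPO), whose level is the pharmacological
target of HIF prolyl-hydroxylase inhibitors:

1. per-cohort GWAS of the (skewed) biomarker after rank-based inverse normal
   transformation (INT),
2. METAL-style inverse-variance-weighted (IVW) fixed-effects meta-analysis
   with allele alignment and QC filtering,
3. stepwise conditional/joint selection of independent signals from summary
   statistics plus an LD reference (GCTA-COJO style),
4. approximate-Bayes-factor colocalization of the protein association with a
   *cis*-eQTL,
5. single-instrument Wald-ratio Mendelian randomization against binary
   disease outcomes and continuous risk markers, and
6. rescaling of the per-SD genetic estimate to the exposure change induced
   by a clinical trial, with "can exclude" upper bounds.

A synthetic-data generator reproduces the statistical structure of the
four-cohort study design (1,210 / 2,954 / 458 / 1,505 samples; pooled
n = 6,127) so that every stage is testable without access to cohort data.

## The synthetic cohorts

`simulate_genotypes()` draws two haplotypes per sample by thresholding a
latent Gaussian AR(1) process across the variant panel. The latent
correlation between variants $i$ and $j$ is $0.5^{|i-j|/\ell}$ with
half-life $\ell$ (`ld_decay`, default 10 index units, positions 1 kb apart),
and each variant's threshold is the quantile of its allele frequency, drawn
uniformly from `maf_range` (default 0.05–0.5). This gives Hardy–Weinberg
marginals with geometrically decaying dosage LD at a cost linear in the
panel — no haplotype reference panel is needed, at the price of an
unrealistic, strictly monotone LD structure (no recombination hotspots, no
allele-frequency/LD coupling). The causal variant's frequency is fixed at
the study value (effect allele 0.62) rather than drawn at random: the
instrument's frequency determines its information content
($\mathrm{SE} \approx 1/\sqrt{2f(1-f)n}$, about 0.019 at the pooled design),
and leaving it random would make every downstream power property a lottery
over frequencies the study did not have.

`simulate_biomarker()` adds unit-variance right-skewed noise to
`beta_causal` × dosage (default 0.063 SD per allele). The noise family is a
standardized log-normal, $({e^{\sigma Z}} - e^{\sigma^2/2})/\mathrm{sd}$,
with `skew` = $\sigma$ (default 0.5, sample skewness ≈ 1.75): a positive,
right-tailed family resembling a serum concentration. The true distribution
of the biomarker is not published; this family is a stand-in, and its
closed-form skewness $(e^{\sigma^2}+2)\sqrt{e^{\sigma^2}-1}$ is what the
moment tests check.

Outcome and eQTL summary statistics are generated directly at the summary
level. Under the mediation model (variant → exposure → outcome) the expected
per-allele log-OR at variant $j$ is $\ln(\mathrm{OR}) \cdot \beta_j$, where
the marginal exposure effect propagates through LD as
$\beta_j = r_{jc}\sqrt{v_c/v_j}\,\beta_c$ with $v = 2f(1-f)$. Binary-trait
standard errors use $1/\sqrt{2f(1-f)\,n_\mathrm{eff}}$ with
$n_\mathrm{eff} = 4/(1/\mathrm{cases} + 1/\mathrm{controls})$. Relatedness,
imputation error, population structure, and case/control ascertainment are
all absent: passing tests demonstrate the *statistical machinery*, not
robustness to those features of real data. In particular the mixed-model
(GRM) adjustment of the original per-cohort scans is deliberately replaced
by OLS, which is the correct model for the generator's unrelated samples.

## The transformation and the estimand

INT maps ranks to normal quantiles,
$\Phi^{-1}\!\big((r - c)/(n - 2c + 1)\big)$ with Blom's $c = 3/8$ and
average ranks for ties. One consequence found while validating the chain is
worth stating plainly: under the generator's *additive* skewed-noise model,
gaussianizing the phenotype changes the estimand. The transform compresses
the long right tail of the noise, so the slope of the transformed phenotype
on dosage is *larger* than the planted raw-scale effect (≈ 0.085 vs 0.063
at `skew = 0.5`). Neither scale is wrong — they are different estimands —
but parameter-recovery checks must compare like with like. The pipeline
therefore exposes `gwas = list(transform = "int" | "none")`:
`"int"` mirrors the study procedure and is the default; recovery tests use
`"none"`, where the planted per-allele effect is the estimand. With real
data, where skewness typically arises from a monotone distortion of a more
nearly Gaussian latent scale, INT approximately *restores* the latent
estimand instead; the additive noise model is the conservative choice for
testing but not a claim about the biology.

## Meta-analysis

Alleles are aligned to a reference orientation by chromosome:position;
swapped records have beta negated and frequency flipped; mismatched allele
pairs are dropped and logged; palindromic variants (A/T, C/G) with MAF
above 0.42 are dropped because strand cannot be resolved from summary data.
IVW pooling uses $w = 1/\mathrm{se}^2$,
$\hat\beta = \sum w\beta/\sum w$, $\mathrm{se} = 1/\sqrt{\sum w}$, with
Cochran's Q and a METAL-style direction string; heterogeneity is reported
but never used for filtering (the analysis is fixed-effects throughout).
A sample-size-weighted z-score scheme (`zscore_meta()`) covers inputs that
carry only t/z statistics, as eQTL meta-analyses often do. QC follows the
study's filters: pre-meta, minor allele count strictly greater than 3,
imputation Info ≥ 0.3, and effect-allele frequency strictly inside (0,1) —
the last implemented as a plausibility filter because monomorphic or
out-of-range frequencies are the only coherent reading of the stated
bounds; post-meta, MAF ≥ 0.01.

## Conditional and joint selection

With phenotypic variance normalized to 1, the genotype cross-products are
approximated from summary data as $B = D^{1/2} R D^{1/2}$, where $R$ is the
reference correlation matrix (entries zeroed beyond a 10 Mb window) and
$D = \mathrm{diag}(v_j n_j)$ absorbs per-variant sample sizes, so cohorts
contributing different subsets meta-analyze correctly. Joint effects solve
$B\,\hat\beta_J = D\,\hat\beta_M$; when the LD matrix carries dosage
variances measured in the same sample as the summary statistics
(`ld_from_genotypes()` fills them; otherwise $2f(1-f)$ is used), this
reproduces individual-level multiple regression exactly, which is the
module's primary oracle. Joint SEs use the pooled residual variance
$(y'y - \hat\beta_J' D \hat\beta_M)/(n - k - 1)$ at the median sample size.

Conditional statistics for a candidate refit the system on
selected ∪ {candidate}; the candidate's SE uses its marginal-implied
residual variance $v_j n_j \mathrm{se}_j^2$, a large-$n$ simplification
under which conditional and marginal statistics coincide exactly on an
orthogonal panel (single-variant $R^2$ is small in this regime, so the
residual-variance reduction from conditioning is second-order). Stepwise
selection is seeded by the smallest marginal p below the threshold
(default 5 × 10⁻⁸), adds the most significant conditional candidate while
one remains below threshold, then backward-drops variants whose joint p
rises above it. Candidates with reference $r^2 > 0.9$ against the selected
set are excluded (GCTA's default, as is the 10 Mb window; the study states
neither). Ties on p break by smaller position, making selection
deterministic. The module targets regional panels of at most a few thousand
variants; no genome-wide sliding-window orchestration is attempted.

## Colocalization

Per-variant evidence is the Wakefield log approximate Bayes factor
$\tfrac12\log(1-r) + z^2 r/2$, $r = W/(V+W)$, with effect-prior SD
$\sqrt{W} = 0.15$ per trait (the conventional default for quantitative
traits in SD units; the study states no priors). Hypothesis posteriors
H0–H4 are assembled in log space with per-variant priors
$p_1 = p_2 = 10^{-4}$, $p_{12} = 10^{-5}$; the two-distinct-variant sum is
computed stably as the product of single-trait sums minus the shared
diagonal, so posteriors remain finite for $|z|$ of 40 and beyond. On
regions of up to four variants the implementation is checked against
explicit enumeration of every causal configuration in plain arithmetic.
An optional p-value pre-filter for the eQTL side mirrors inputs distributed
only below an FDR cutoff; it is off by default because filtering
colocalization inputs is nonstandard and weakens H3/H4 discrimination.

## Wald ratio and trial rescaling

The causal effect per exposure-SD is $\beta_Y/\beta_X$. The default SE is
first-order ($\mathrm{se}_Y/|\beta_X|$); the second-order form adds the
exposure-uncertainty term
$\beta_Y^2\mathrm{se}_X^2/\beta_X^4$. For a *null* outcome effect the
first-order interval's coverage is exact by construction, which is what the
calibration check exercises; for non-null effects at this design's
instrument strength ($z \approx 3.4$) the first-order interval ignores a
non-negligible error source and under-covers, so recovery-of-truth checks
use the second-order method. Only a single *cis* instrument is supported:
with one variant there is no within-locus test of horizontal pleiotropy,
and multi-instrument estimators are out of scope.

Trial rescaling expresses an intervention's biomarker response in exposure
SD ($27.1/61 \approx 0.44$ SD for the default record), divides by the
per-allele effect (0.063 SD) to give the per-allele factor ≈ 7.05, and
multiplies the log-odds point and CI bounds by the SD change — equivalently
raising odds ratios to the power 0.44. The upper rescaled bound in the harm
direction is reported as the largest adverse effect compatible with the
genetic data. Rescaling published per-SD odds ratios uses their printed
point estimates and CIs as inputs; because published values are rounded,
re-derived rescaled CIs can differ in the last digit from published ones,
and only point estimates are treated as reproducible.

## PheWAS

One variant against many traits: continuous traits are INT-transformed and
fit by OLS, binary traits by logistic regression, each on its complete
cases; traits with fewer than two distinct values are emitted as
`degenerate` rows without statistics, so the output always has one row per
trait. The significance flag uses a fixed 5 × 10⁻⁸ threshold with no
further multiplicity correction, mirroring how such scans are reported.

## Numerical conventions

* Two-sided p-values come from the normal approximation to the t/z
  statistic (the summary-statistics convention) and are floored at
  1e-320 rather than underflowing to 0.
* Coordinates are 1-based; intervals closed. Variants are matched across
  tables by chromosome:position, with snp_id as tiebreaker.
* All randomness flows from explicit seeds; every generator is a pure
  function of (config, seed), and `run_pipeline()` reruns byte-identically.
* LD matrices must be symmetric with unit diagonal and positive
  semi-definite within 1e-8; singular selected-set submatrices are refused
  with the offending pair named.

## Problem sizes used by the test suite

The suite exercises the chain at the study's own design sizes where that is
the point (pooled n = 6,127 recovery; eQTL n = 861 colocalization), and at
deliberately modest sizes elsewhere: 20-seed batteries for the
colocalization and selection properties, 200–500 summary-level replicates
for MR calibration, n = 50,000 single-variant draws for frequency
concentration, and n = 10,000 × 60-variant regions for the two-signal
selection checks. These sizes were chosen to make the binomial tolerances
of each check tight enough to be informative while keeping the whole suite
comfortably interactive.

## Known limitations

* The LD model has no haplotype-panel realism; r² between thresholded
  dosages is attenuated relative to the latent AR(1) correlation.
* No population structure or admixture is simulated, although the emulated
  study pooled European and African-ancestry cohorts; single-study variants
  are retained and flagged rather than resolved.
* The eQTL stage models only a z/sample-size meta scale, not the underlying
  expression pipeline.
* Colocalization assumes at most one causal variant per trait in the
  region (no SuSiE-style multi-causal decomposition).
* The published colocalization posterior and locus counts depend on the
  deposited cohort data and are not recomputable here; the package's
  simulation-based checks validate the machinery, not those numbers.
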