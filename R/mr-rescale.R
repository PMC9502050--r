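#' Single-instrument Wald-ratio Mendelian randomization estimate
#'
#' Causal effect of the exposure on the outcome using one genetic instrument:
#' `ratio = beta_outcome / beta_exposure`. The first-order delta-method SE is
#' `se_outcome / |beta_exposure|`; the second-order SE adds the
#' exposure-uncertainty term,
#' `sqrt(se_out^2/b_exp^2 + b_out^2 * se_exp^2 / b_exp^4)`. A 95% normal CI
#' is attached, and for binary outcomes (log-odds scale) the exponentiated
#' odds-ratio triple as well.
#'
#' @param beta_exposure per-allele exposure effect (nonzero), exposure-SD.
#' @param se_exposure its standard error.
#' @param beta_outcome per-allele outcome effect (log-odds or trait units).
#' @param se_outcome its standard error.
#' @param method delta-method order for the SE.
#' @param binary_outcome is the outcome on the log-odds scale?
#' @param instrument optional instrument variant id, carried in the result.
#' @return object of class `wald_estimate`: ratio, se, ci, p, or_scale
#'   (for binary outcomes), method, instrument and the input associations.
#' @examples
#' wald_ratio(0.063, 0.0186, 0.0315, 0.0063)
#' @export
wald_ratio <- function(beta_exposure, se_exposure, beta_outcome, se_outcome,
                       method = c("first_order", "second_order"),
                       binary_outcome = TRUE, instrument = NA_character_) {
  method <- match.arg(method)
  if (beta_exposure == 0)
    stopf("zero exposure effect: invalid instrument for a Wald ratio")
  ratio <- beta_outcome / beta_exposure
  se <- se_outcome / abs(beta_exposure)
  if (method == "second_order")
    se <- sqrt(se_outcome^2 / beta_exposure^2 +
               beta_outcome^2 * se_exposure^2 / beta_exposure^4)
  zcrit <- stats::qnorm(0.975)
  ci <- ratio + c(-1, 1) * zcrit * se
  out <- list(ratio = ratio, se = se, ci = ci,
              p = pnorm2(ratio / se),
              or_scale = if (binary_outcome)
                list(or = exp(ratio), ci = exp(ci)) else NULL,
              method = method, instrument = instrument,
              beta_exposure = beta_exposure, se_exposure = se_exposure,
              beta_outcome = beta_outcome, se_outcome = se_outcome)
  class(out) <- "wald_estimate"
  out
}

#' @export
print.wald_estimate <- function(x, ...) {
  cat(sprintf("Wald ratio (%s): %.4f [%.4f, %.4f], p = %.3g\n",
              x$method, x$ratio, x$ci[1], x$ci[2], x$p))
  if (!is.null(x$or_scale))
    cat(sprintf("  OR per exposure-SD: %.3f [%.3f, %.3f]\n",
                x$or_scale$or, x$or_scale$ci[1], x$or_scale$ci[2]))
  invisible(x)
}

#' Pool outcome associations for one instrument across sources
#'
#' Fixed-effects inverse-variance pooling of the instrument's outcome
#' association from several GWAS sources (e.g. a biobank scan plus a public
#' consortium GWAS) before the Wald step. Delegates to [ivw_meta()].
#'
#' @param ... summary-statistics rows (one variant each), or a single list
#'   of them.
#' @return a single pooled summary-statistics row.
#' @export
combine_outcome_sources <- function(...) {
  sources <- list(...)
  if (length(sources) == 1 && !is.data.frame(sources[[1]]))
    sources <- sources[[1]]
  pooled <- ivw_meta(sources)
  if (nrow(pooled) != 1)
    stopf("outcome sources must all describe the same single variant")
  pooled
}

#' Map between exposure-SD and natural biomarker units
#'
#' @param sd_in_natural_units natural units (IU/L) per 1 exposure-SD;
#'   default 5.1 IU/L.
#' @export
unit_map <- function(sd_in_natural_units = 5.1) {
  if (sd_in_natural_units <= 0) stopf("sd_in_natural_units must be positive")
  structure(list(sd_in_natural_units = sd_in_natural_units),
            class = "unit_map")
}

#' Convert an SD-scale effect to natural units
#'
#' @param beta_sd effect in exposure-SD units.
#' @param map a [unit_map()].
#' @return effect in natural units (sign-preserving product).
#' @examples
#' convert_units(0.063, unit_map(5.1))  # 0.32 IU/L
#' @export
convert_units <- function(beta_sd, map = unit_map()) {
  beta_sd * map$sd_in_natural_units
}

#' Scaling factor from a trial-induced exposure change
#'
#' Expresses a trial's biomarker response in exposure-SD
#' (`scaling_sd = median_change / baseline_sd`) and divides by the
#' instrument's per-allele effect to obtain the per-allele scaling factor
#' applied to genetic estimates.
#'
#' @param trial a [trial_effect()].
#' @param beta_exposure_sd per-allele exposure effect in SD (nonzero).
#' @return list: `factor` (per-allele), `scaling_sd` (trial change in SD).
#' @examples
#' scaling_factor(trial_effect(27.1, 61), 0.063)  # factor 7.05
#' @export
scaling_factor <- function(trial, beta_exposure_sd) {
  if (trial$baseline_sd <= 0) stopf("baseline_sd must be positive")
  if (beta_exposure_sd == 0) stopf("beta_exposure_sd must be nonzero")
  scaling_sd <- trial$median_change / trial$baseline_sd
  list(factor = scaling_sd / beta_exposure_sd, scaling_sd = scaling_sd)
}

#' Rescale a per-SD genetic estimate to a trial-induced exposure change
#'
#' Multiplies the log-odds (or linear) point estimate and both confidence
#' bounds by `scaling_sd`; odds ratios are therefore raised to the power
#' `scaling_sd`. The exclusion bound is the rescaled confidence limit in the
#' harm direction, quoted as the largest adverse effect compatible with the
#' genetic data.
#'
#' @param estimate a [wald_ratio()] result (per exposure-SD).
#' @param scaling_sd trial-induced exposure change in SD units.
#' @param harm_direction which tail counts as harm: `"increase"` (upper
#'   bound, e.g. disease odds) or `"decrease"` (lower bound).
#' @return object of class `rescaled_effect`: effect, ci, or_scale,
#'   exclusion_bound, scaling_sd, factor_per_allele.
#' @export
rescale_effect <- function(estimate, scaling_sd,
                           harm_direction = c("increase", "decrease")) {
  harm_direction <- match.arg(harm_direction)
  eff <- estimate$ratio * scaling_sd
  ci <- estimate$ci * scaling_sd
  if (scaling_sd < 0) ci <- rev(ci)
  binary <- !is.null(estimate$or_scale)
  or_scale <- if (binary) list(or = exp(eff), ci = exp(ci)) else NULL
  bound <- if (harm_direction == "increase") ci[2] else ci[1]
  if (binary) bound <- exp(bound)
  structure(list(effect = eff, ci = ci, or_scale = or_scale,
                 exclusion_bound = bound, harm_direction = harm_direction,
                 scaling_sd = scaling_sd,
                 factor_per_allele = scaling_sd / estimate$beta_exposure,
                 per_sd = estimate),
            class = "rescaled_effect")
}

#' @export
print.rescaled_effect <- function(x, ...) {
  if (!is.null(x$or_scale)) {
    cat(sprintf("rescaled OR (x %.3f SD): %.3f [%.3f, %.3f]; can exclude OR %s %.3f\n",
                x$scaling_sd, x$or_scale$or, x$or_scale$ci[1], x$or_scale$ci[2],
                if (x$harm_direction == "increase") ">" else "<",
                x$exclusion_bound))
  } else {
    cat(sprintf("rescaled effect (x %.3f SD): %.3f [%.3f, %.3f]; can exclude %s %.3f\n",
                x$scaling_sd, x$effect, x$ci[1], x$ci[2],
                if (x$harm_direction == "increase") ">" else "<",
                x$exclusion_bound))
  }
  invisible(x)
}
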