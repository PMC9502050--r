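#' Single-variant phenome-wide association scan
#'
#' Tests one variant's dosage against every trait in a trait matrix.
#' Continuous traits are inverse-normal transformed (see
#' [inverse_normal_transform()]) then fit by linear regression; binary traits
#' by logistic regression. Each trait uses its complete cases; traits with
#' fewer than 2 distinct observed values are reported with status
#' `"degenerate"` and no statistics. Rows are ordered by ascending p-value
#' (degenerate rows last), one row per input trait.
#'
#' @param dosage numeric dosage vector at the scanned variant.
#' @param traits matrix or data.frame, samples x traits.
#' @param trait_type character vector, `"continuous"` or `"binary"` per trait.
#' @param threshold significance level for the `significant` flag
#'   (default 5e-8; no further multiplicity correction is applied).
#' @param int_offset rank offset for the inverse normal transform.
#' @return data.frame of class `phewas_table`: trait, trait_type, beta, se,
#'   p, n, significant, status.
#' @export
phewas_scan <- function(dosage, traits, trait_type, threshold = 5e-8,
                        int_offset = 3 / 8) {
  traits <- as.matrix(traits)
  if (length(dosage) != nrow(traits))
    stopf("dosage length %d != trait matrix rows %d",
          length(dosage), nrow(traits))
  if (length(trait_type) != ncol(traits))
    stopf("trait_type length must match trait count")
  labels <- colnames(traits) %||% sprintf("trait%04d", seq_len(ncol(traits)))

  one <- function(j) {
    y <- traits[, j]
    ok <- !is.na(y) & !is.na(dosage)
    yv <- y[ok]; xv <- dosage[ok]
    if (length(unique(yv)) < 2) {
      return(data.frame(trait = labels[j], trait_type = trait_type[j],
                        beta = NA_real_, se = NA_real_, p = NA_real_,
                        n = sum(ok), significant = FALSE,
                        status = "degenerate", stringsAsFactors = FALSE))
    }
    if (trait_type[j] == "continuous") {
      yt <- inverse_normal_transform(yv, int_offset)
      xc <- xv - mean(xv)
      sxx <- sum(xc^2)
      beta <- sum(xc * yt) / sxx
      rss <- sum((yt - mean(yt) - beta * xc)^2)
      se <- sqrt(rss / (length(yt) - 2) / sxx)
    } else {
      fit <- stats::glm(yv ~ xv, family = stats::binomial())
      cf <- summary(fit)$coefficients
      beta <- cf["xv", 1]
      se <- cf["xv", 2]
    }
    p <- pnorm2(beta / se)
    data.frame(trait = labels[j], trait_type = trait_type[j],
               beta = beta, se = se, p = p, n = length(yv),
               significant = p < threshold, status = "ok",
               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(seq_len(ncol(traits)), one))
  out <- out[order(out$p, na.last = TRUE), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("phewas_table", "data.frame")
  out
}
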