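## Error metrics and the across-modality statistics battery.

#' Root-mean-square error
#'
#' @param yTrue,yPred equal-length numeric series.
#' @return `sqrt(mean((yTrue - yPred)^2))`.
#' @export
rmse <- function(yTrue, yPred) {
  if (length(yTrue) != length(yPred) || length(yTrue) == 0L)
    stopNamed("myofuse_length_mismatch",
              "series must be non-empty and equal-length")
  sqrt(mean((yTrue - yPred)^2))
}

#' Range-normalised RMSE
#'
#' Expresses an RMSE as a percentage of the measured signal's range.
#'
#' @param rmseVal RMSE in the signal's units.
#' @param yTrue the measured series whose range normalises the error.
#' @return `100 * rmseVal / (max(yTrue) - min(yTrue))`, in percent.
#' @export
nrmse <- function(rmseVal, yTrue) {
  rng <- max(yTrue) - min(yTrue)
  if (rng <= 0)
    stopNamed("myofuse_zero_range",
              "measured series has zero range; nRMSE undefined")
  100 * rmseVal / rng
}

#' Adjusted coefficient of determination for nonlinear regression
#'
#' \eqn{R^2_{adj} = 1 - \frac{N-1}{N-1-p}(1 - R^2)} with
#' \eqn{R^2 = 1 - RSS/TSS}, where `N` is the training-set size and `p`
#' the number of variables in the regression model.
#'
#' @param yTrue measured series.
#' @param yPred predicted series.
#' @param N training-set size.
#' @param p number of model variables (feature columns).
#' @return adjusted R-squared (at most 1; can be negative).
#' @export
adjustedR2 <- function(yTrue, yPred, N, p) {
  if (length(yTrue) != length(yPred) || length(yTrue) == 0L)
    stopNamed("myofuse_length_mismatch",
              "series must be non-empty and equal-length")
  if (N - 1 - p <= 0)
    stopNamed("myofuse_invalid_argument",
              "need N - 1 - p > 0 (got N = %d, p = %d)", N, p)
  tss <- sum((yTrue - mean(yTrue))^2)
  if (tss == 0)
    stopNamed("myofuse_zero_range", "yTrue is constant; R-squared undefined")
  r2 <- 1 - sum((yTrue - yPred)^2) / tss
  1 - (N - 1) / (N - 1 - p) * (1 - r2)
}

#' One-way ANOVA with Tukey-Kramer comparisons across sensing modalities
#'
#' Compares an error metric (typically per-replicate overall RMSE)
#' across modality groups by one-way ANOVA; when the group effect is
#' significant at `alpha`, unequal-n Tukey-Kramer pairwise comparisons
#' (studentized-range distribution) are run, otherwise pairwise testing
#' is skipped.
#'
#' @param tbl data.frame with columns `modality` (group label) and
#'   `value` (the metric).
#' @param alpha significance level.
#' @return list: `F`, `p`, `significant`, `pairwise` (data.frame or
#'   NULL), `alpha`.
#' @export
compareModalities <- function(tbl, alpha = 0.05) {
  stopifnot(all(c("modality", "value") %in% names(tbl)))
  tbl$modality <- factor(tbl$modality)
  counts <- table(tbl$modality)
  if (length(counts) < 2L)
    stopNamed("myofuse_invalid_argument", "need at least two groups")
  if (any(counts < 2L))
    stopNamed("myofuse_invalid_argument",
              "every group needs at least two observations")
  gm <- tapply(tbl$value, tbl$modality, mean)
  ssb <- sum(counts * (gm - mean(tbl$value))^2)
  if (ssb <= 1e-12 * max(1e-300, sum((tbl$value - mean(tbl$value))^2), 1e-12)) {
    return(list(F = 0, p = 1, significant = FALSE, pairwise = NULL,
                alpha = alpha))
  }
  fit <- stats::aov(value ~ modality, data = tbl)
  sm <- summary(fit)[[1]]
  Fval <- sm[["F value"]][1]
  pval <- sm[["Pr(>F)"]][1]
  pw <- NULL
  if (pval < alpha) {
    tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$modality
    pw <- data.frame(
      comparison = rownames(tk),
      diff = tk[, "diff"],
      pAdj = tk[, "p adj"],
      significant = tk[, "p adj"] < alpha,
      row.names = NULL
    )
  }
  list(F = Fval, p = pval, significant = pval < alpha, pairwise = pw,
       alpha = alpha)
}
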