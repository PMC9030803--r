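# The five evaluation metrics: R2, RMSE, NRMSE, Pearson's rho and
# Spearman's gamma.
#
# R2 defaults to the explained-variance form
#   sum((y_pred - mean(y_obs))^2) / sum((y_obs - mean(y_obs))^2),
# which can exceed 1 for a biased predictor; the standard 1 - SSE/SST form
# is available via `r2_form`.  Both are reported in evaluation records.

#' Spearman rank correlation
#'
#' Uses the tie-free closed form `1 - 6 sum(d^2) / (N (N^2 - 1))` when
#' neither vector has ties (where d are the rank differences), and the
#' Pearson correlation of midranks otherwise; the two coincide without
#' ties.  Returns 0 when either vector has zero rank variance (a
#' constant carries no ranking information).
#'
#' @param y_obs,y_pred Numeric vectors of equal length.
#' @return Rank correlation in [-1, 1].
#' @export
spearman_gamma <- function(y_obs, y_pred) {
  n <- length(y_obs)
  if (length(y_pred) != n) stop("length mismatch")
  if (stats::sd(y_obs) == 0 || stats::sd(y_pred) == 0) return(0)
  r1 <- rank(y_obs)
  r2 <- rank(y_pred)
  ties <- anyDuplicated(y_obs) > 0 || anyDuplicated(y_pred) > 0
  if (!ties) {
    d <- r1 - r2
    1 - 6 * sum(d^2) / (n * (n^2 - 1))
  } else {
    stats::cor(r1, r2)
  }
}

#' Regression evaluation metrics
#'
#' Computes the five metrics used throughout the pipeline: coefficient of
#' determination R2 (see `r2_form`), root-mean-square error, RMSE
#' normalized by the sample standard deviation of the observations,
#' Pearson's correlation rho, and Spearman's rank correlation gamma.
#'
#' @param y_obs Observed values (length >= 3, non-constant).
#' @param y_pred Predicted values.
#' @param r2_form `"as_printed"` (explained-variance ratio, default) or
#'   `"one_minus_sse_over_sst"`.
#' @return Named numeric vector with elements `r2`, `rmse`, `nrmse`,
#'   `pearson_rho`, `spearman_gamma` (plus `r2_alt`, the other R2 form).
#' @export
regression_metrics <- function(y_obs, y_pred,
                               r2_form = c("as_printed",
                                           "one_minus_sse_over_sst")) {
  r2_form <- match.arg(r2_form)
  n <- length(y_obs)
  if (length(y_pred) != n) stop("length mismatch")
  if (n < 3) stop("metrics require at least 3 points")
  sd_obs <- stats::sd(y_obs)
  if (sd_obs == 0) stop("y_obs has zero variance; NRMSE/rho/gamma undefined")
  ybar <- mean(y_obs)
  sst <- sum((y_obs - ybar)^2)
  r2_printed <- sum((y_pred - ybar)^2) / sst
  r2_standard <- 1 - sum((y_obs - y_pred)^2) / sst
  rmse <- sqrt(mean((y_obs - y_pred)^2))
  rho <- if (stats::sd(y_pred) == 0) 0 else stats::cor(y_obs, y_pred)
  out <- c(
    r2 = if (r2_form == "as_printed") r2_printed else r2_standard,
    rmse = rmse,
    nrmse = rmse / sd_obs,
    pearson_rho = rho,
    spearman_gamma = spearman_gamma(y_obs, y_pred),
    r2_alt = if (r2_form == "as_printed") r2_standard else r2_printed)
  out
}
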