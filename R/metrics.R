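#' Paired sensor-versus-reference performance metrics
#'
#' Computes the evaluation statistics used throughout the pipeline on
#' complete-case pairs: Pearson correlation `r`, coefficient of
#' determination `r2` in its deviance form
#' \eqn{R^2 = 1 - \sum(y-\hat y)^2 / \sum(y-\bar y)^2} (which can be
#' negative, and differs from `r^2` unless the fit is the least-squares
#' line), root-mean-square error `rmse`, mean absolute error `mae`, and
#' mean bias `mb = mean(yhat - y)`.
#'
#' Pairs where either side is missing are dropped before anything is
#' computed; no imputation is performed. If either series has zero
#' variance, `r` (and `r2` when `y` is constant) are undefined and returned
#' as `NA` with `r_defined = FALSE`, never silently zero.
#'
#' @param data A data frame holding the paired values.
#' @param y,yhat Columns of `data` (tidy-eval): reference values and
#'   sensor/model values, in ug/m3.
#' @return A one-row tibble: `n`, `r`, `r_defined`, `r2`, `rmse`, `mae`,
#'   `mb`.
#' @examples
#' d <- tibble::tibble(obs = c(3, 5, 7), est = c(3, 5, 7))
#' paired_metrics(d, obs, est)
#' @export
paired_metrics <- function(data, y, yhat) {
  yv <- dplyr::pull(data, {{ y }})
  fv <- dplyr::pull(data, {{ yhat }})
  ok <- is.finite(yv) & is.finite(fv)
  yv <- yv[ok]
  fv <- fv[ok]
  n <- length(yv)
  if (n < 2) stop("paired_metrics needs at least 2 complete pairs", call. = FALSE)
  resid <- fv - yv
  rmse <- sqrt(mean(resid^2))
  mae <- mean(abs(resid))
  mb <- mean(resid)
  ss_tot <- sum((yv - mean(yv))^2)
  var_y <- stats::var(yv)
  var_f <- stats::var(fv)
  r_defined <- var_y > 0 && var_f > 0
  r <- if (r_defined) stats::cor(yv, fv) else NA_real_
  r2 <- if (ss_tot > 0) 1 - sum(resid^2) / ss_tot else NA_real_
  tibble::tibble(
    n = n, r = r, r_defined = r_defined, r2 = r2,
    rmse = rmse, mae = mae, mb = mb
  )
}

#' RMSE normalised to the reference interquartile range
#'
#' The RMSE of a paired comparison divided by the interquartile range of
#' the reference-station concentration distribution, making sensor error
#' comparable across periods with different pollution levels.
#'
#' @inheritParams paired_metrics
#' @param ref_all Numeric vector: the full reference concentration series
#'   whose IQR (75th minus 25th percentile, linear-interpolation quantiles)
#'   is the normaliser. Needs at least 4 finite values.
#' @return A one-row tibble: `nrmse`, `rmse`, `iqr`, `nrmse_defined`
#'   (`FALSE` when the IQR is zero).
#' @export
nrmse <- function(data, y, yhat, ref_all) {
  ref_all <- ref_all[is.finite(ref_all)]
  if (length(ref_all) < 4) stop("nrmse needs >= 4 finite reference values", call. = FALSE)
  m <- paired_metrics(data, {{ y }}, {{ yhat }})
  iqr <- unname(diff(stats::quantile(ref_all, c(0.25, 0.75), type = 7)))
  defined <- iqr > 0
  tibble::tibble(
    nrmse = if (defined) m$rmse / iqr else NA_real_,
    rmse = m$rmse,
    iqr = iqr,
    nrmse_defined = defined
  )
}

#' Measurement uncertainty from corrected-sensor deviations
#'
#' Fits a normal distribution to the deviations of corrected sensor
#' measurements from the reference, forms the t-based confidence interval
#' for the mean deviation, and expresses it as a percentage of the
#' regulatory limit value for continuous PM2.5 measurement (default
#' 24 ug/m3). Two variants are reported, since "dividing the confidence
#' interval by the limit value" admits both readings: `uncertainty_pct`
#' uses the larger absolute CI bound, `uncertainty_width_pct` the CI width.
#'
#' @param deviations Numeric vector: corrected sensor minus reference
#'   (daily values), ug/m3. At least 3 finite values.
#' @param limit_value Limit value in ug/m3 (default 24).
#' @param ci_level Confidence level (default 0.95).
#' @return A one-row tibble: `n`, `mean_dev`, `sd_dev`, `ci_lower`,
#'   `ci_upper`, `uncertainty_pct`, `uncertainty_width_pct`.
#' @export
cen_uncertainty <- function(deviations, limit_value = 24, ci_level = 0.95) {
  stopifnot(limit_value > 0, ci_level > 0, ci_level < 1)
  d <- deviations[is.finite(deviations)]
  n <- length(d)
  if (n < 3) stop("cen_uncertainty needs at least 3 deviations", call. = FALSE)
  m <- mean(d)
  s <- stats::sd(d)
  half <- stats::qt(1 - (1 - ci_level) / 2, df = n - 1) * s / sqrt(n)
  lo <- m - half
  hi <- m + half
  tibble::tibble(
    n = n, mean_dev = m, sd_dev = s, ci_lower = lo, ci_upper = hi,
    uncertainty_pct = 100 * max(abs(lo), abs(hi)) / limit_value,
    uncertainty_width_pct = 100 * (hi - lo) / limit_value
  )
}
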