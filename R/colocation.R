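#' Configuration for the robust colocation fit
#'
#' @param tuning_constant Bisquare tuning constant `c` (default 4.685, the
#'   conventional value giving 95% efficiency under Gaussian errors).
#' @param include_intercept Fit an intercept (default `FALSE`: the
#'   calibration is through the origin, matching the finding that the
#'   intercept is statistically insignificant for daily averages).
#' @param include_rh Add relative humidity as a covariate (default
#'   `FALSE`, for the same reason).
#' @param max_iterations IRLS iteration cap (default 200; the MAD rescale
#'   makes the tail of the iteration slow on small samples).
#' @param tol Convergence tolerance on the coefficient change (default 1e-8).
#' @return A list of class `robust_fit_config`.
#' @export
robust_fit_config <- function(tuning_constant = 4.685,
                              include_intercept = FALSE,
                              include_rh = FALSE,
                              max_iterations = 200L,
                              tol = 1e-8) {
  stopifnot(tuning_constant > 0, max_iterations >= 1, tol > 0)
  structure(
    list(
      weight_function = "bisquare",
      tuning_constant = tuning_constant,
      include_intercept = include_intercept,
      include_rh = include_rh,
      max_iterations = as.integer(max_iterations),
      tol = tol
    ),
    class = "robust_fit_config"
  )
}

bisquare_weights <- function(u, c) {
  w <- (1 - (u / c)^2)^2
  w[abs(u) >= c] <- 0
  w
}

#' Robust colocation calibration by IRLS with bisquare weights
#'
#' Regresses daily sensor output on daily reference concentrations by
#' iteratively reweighted least squares with the bisquare (biweight)
#' weight function: `w(u) = (1 - (u/c)^2)^2` for `|u| < c`, else 0, where
#' `u` is the residual scaled by 1.4826 times the median absolute
#' deviation (re-estimated each iteration) and `c` is the tuning constant.
#' The slope is the sensor gain; its reciprocal is the correction factor
#' to apply to factory-calibrated output. Coefficient p-values come from
#' the final weighted least-squares fit.
#'
#' @param data A data frame of paired (daily) values.
#' @param sensor,ref Columns of `data` (tidy-eval): sensor output and
#'   reference concentration, ug/m3.
#' @param cfg A [robust_fit_config()].
#' @param rh Optional column with relative humidity, required when
#'   `cfg$include_rh` is `TRUE`.
#' @return An object of class `aq_calibration`: coefficient table, `slope`,
#'   `correction_factor = 1/slope`, final `weights`, `scale`, `iterations`,
#'   `converged`, plus raw and corrected [paired_metrics()] and the
#'   [cen_uncertainty()] of the corrected deviations.
#' @examples
#' d <- generate_colocation(seed = 7)
#' fit <- robust_fit(d, sensor, ref)
#' glance(fit)$correction_factor
#' @export
robust_fit <- function(data, sensor, ref, cfg = robust_fit_config(), rh = NULL) {
  y <- dplyr::pull(data, {{ sensor }})
  x <- dplyr::pull(data, {{ ref }})
  rh_v <- if (cfg$include_rh) dplyr::pull(data, {{ rh }}) else NULL
  ok <- is.finite(y) & is.finite(x)
  if (cfg$include_rh) ok <- ok & is.finite(rh_v)
  y <- y[ok]
  x <- x[ok]
  if (length(y) < 5) stop("robust_fit needs at least 5 paired values", call. = FALSE)

  X <- cbind(ref = x)
  if (cfg$include_rh) X <- cbind(X, rh = rh_v[ok])
  if (cfg$include_intercept) X <- cbind(`(Intercept)` = 1, X)

  w <- rep(1, length(y))
  fit <- stats::lm.wfit(X, y, w)
  beta <- fit$coefficients
  converged <- FALSE
  iter <- 0L
  scale <- NA_real_
  for (iter in seq_len(cfg$max_iterations)) {
    resid <- y - drop(X %*% beta)
    scale <- stats::mad(resid, center = 0)
    if (!is.finite(scale) || scale < 1e-10 * max(1, stats::mad(y, center = 0))) {
      # (near-)perfect fit: weights are all 1 and the iteration is done
      w <- rep(1, length(y))
      converged <- TRUE
      break
    }
    w <- bisquare_weights(resid / scale, cfg$tuning_constant)
    if (all(w == 0)) stop("robust_fit breakdown: all observations down-weighted to zero", call. = FALSE)
    fit <- stats::lm.wfit(X, y, w)
    delta <- max(abs(fit$coefficients - beta))
    beta <- fit$coefficients
    if (delta < cfg$tol * max(1, max(abs(beta)))) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    cond <- structure(
      class = c("aq_robust_fit_nonconvergence", "error", "condition"),
      list(
        message = sprintf("robust_fit did not converge in %d iterations", cfg$max_iterations),
        call = sys.call(-1), last_coefficients = beta
      )
    )
    stop(cond)
  }

  # inference from the final weighted fit
  wlm <- stats::lm(y ~ X - 1, weights = w)
  # a noiseless calibration makes this summary complain about a perfect
  # fit; the coefficient table is still what we want
  sm <- suppressWarnings(summary(wlm)$coefficients)
  rownames(sm) <- colnames(X)
  coef_tbl <- tibble::tibble(
    term = rownames(sm),
    estimate = sm[, "Estimate"],
    std.error = sm[, "Std. Error"],
    statistic = sm[, "t value"],
    p.value = sm[, "Pr(>|t|)"]
  )
  slope <- beta[["ref"]]
  if (!is.finite(slope) || slope == 0) stop("robust_fit produced a degenerate slope", call. = FALSE)

  paired <- tibble::tibble(ref = x, sensor = y, corrected = y / slope)
  raw_metrics <- paired_metrics(paired, ref, sensor)
  corrected_metrics <- paired_metrics(paired, ref, corrected)
  uncertainty <- if (length(y) >= 3) {
    cen_uncertainty(paired$corrected - paired$ref)
  } else {
    NULL
  }
  structure(
    list(
      coefficients = coef_tbl,
      slope = slope,
      correction_factor = 1 / slope,
      weights = w,
      scale = scale,
      iterations = iter,
      converged = converged,
      cfg = cfg,
      paired = paired,
      raw_metrics = raw_metrics,
      corrected_metrics = corrected_metrics,
      uncertainty = uncertainty
    ),
    class = "aq_calibration"
  )
}

#' @export
print.aq_calibration <- function(x, ...) {
  cat(sprintf(
    "<aq_calibration> slope %.4f (correction factor %.4f), %d iterations\n",
    x$slope, x$correction_factor, x$iterations
  ))
  print(x$coefficients)
  invisible(x)
}

#' Tidy a robust calibration fit
#' @param x An `aq_calibration` from [robust_fit()].
#' @param ... Unused.
#' @return The coefficient tibble (`term`, `estimate`, `std.error`,
#'   `statistic`, `p.value`).
#' @export
tidy.aq_calibration <- function(x, ...) x$coefficients

#' One-row summary of a robust calibration fit
#' @param x An `aq_calibration`.
#' @param ... Unused.
#' @return Tibble with slope, correction factor, convergence info, raw and
#'   corrected RMSE/MAE and the CEN-style uncertainty percentage.
#' @export
glance.aq_calibration <- function(x, ...) {
  tibble::tibble(
    slope = x$slope,
    correction_factor = x$correction_factor,
    iterations = x$iterations,
    converged = x$converged,
    rmse_raw = x$raw_metrics$rmse,
    rmse_corrected = x$corrected_metrics$rmse,
    mae_raw = x$raw_metrics$mae,
    mae_corrected = x$corrected_metrics$mae,
    uncertainty_pct = if (is.null(x$uncertainty)) NA_real_ else x$uncertainty$uncertainty_pct
  )
}

#' @export
autoplot.aq_calibration <- function(object, ...) {
  ggplot2::ggplot(object$paired, ggplot2::aes(.data$ref, .data$sensor)) +
    ggplot2::geom_point(ggplot2::aes(alpha = object$weights)) +
    ggplot2::geom_abline(slope = object$slope, intercept = 0, color = "firebrick") +
    ggplot2::guides(alpha = "none") +
    ggplot2::labs(
      x = expression(Reference ~ PM[2.5] ~ (mu * g ~ m^-3)),
      y = expression(Sensor ~ PM[2.5] ~ (mu * g ~ m^-3))
    )
}

#' Mean-shift correction of a sensor series against a reference
#'
#' Applies a gain and shifts the sensor mean to match the reference mean
#' over their paired records: `corrected = gain * sensor + (mean(ref) -
#' mean(gain * sensor))`.
#'
#' @param data A data frame with the two series.
#' @param sensor,ref Columns of `data` (tidy-eval).
#' @param gain Multiplicative correction applied before the shift
#'   (default 1).
#' @return `data` with an added `corrected` column (NA where the sensor is
#'   missing).
#' @export
mean_shift_correction <- function(data, sensor, ref, gain = 1) {
  y <- dplyr::pull(data, {{ sensor }})
  r <- dplyr::pull(data, {{ ref }})
  ok <- is.finite(y) & is.finite(r)
  if (!any(ok)) stop("mean_shift_correction: no overlapping records", call. = FALSE)
  shift <- mean(r[ok]) - mean(gain * y[ok])
  dplyr::mutate(data, corrected = gain * {{ sensor }} + shift)
}

#' Sensor-to-sensor correlation matrix
#'
#' Pearson correlation between every pair of sensors on hours (or daily
#' means) where both report; pairs with insufficient overlap are `NA`.
#'
#' @param data A network tibble.
#' @param resolution `"hourly"` or `"daily"` (daily means of available
#'   hours).
#' @param min_pairs Minimum overlapping records for a defined entry
#'   (default 24).
#' @return A symmetric correlation matrix with unit diagonal, sensors in
#'   column order of first appearance.
#' @export
pairwise_correlation_matrix <- function(data, resolution = c("hourly", "daily"),
                                        min_pairs = 24) {
  resolution <- match.arg(resolution)
  lcs <- dplyr::filter(data, .data$source == "lcs")
  if (length(unique(lcs$sensor_id)) < 2) {
    stop("pairwise_correlation_matrix needs at least 2 sensors", call. = FALSE)
  }
  series <- if (resolution == "daily") {
    lcs |>
      dplyr::mutate(t = day_of(.data$timestamp)) |>
      dplyr::group_by(.data$sensor_id, .data$t) |>
      dplyr::summarise(pm25 = mean(.data$pm25, na.rm = TRUE), .groups = "drop") |>
      dplyr::mutate(pm25 = ifelse(is.nan(.data$pm25), NA_real_, .data$pm25))
  } else {
    lcs |> dplyr::select("sensor_id", t = "timestamp", "pm25")
  }
  wide <- tidyr::pivot_wider(series, names_from = "sensor_id", values_from = "pm25")
  m <- as.matrix(wide[, -1, drop = FALSE])
  ids <- colnames(m)
  k <- length(ids)
  out <- matrix(NA_real_, k, k, dimnames = list(ids, ids))
  diag(out) <- 1
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      ok <- is.finite(m[, i]) & is.finite(m[, j])
      if (sum(ok) >= min_pairs && stats::sd(m[ok, i]) > 0 && stats::sd(m[ok, j]) > 0) {
        out[i, j] <- out[j, i] <- stats::cor(m[ok, i], m[ok, j])
      }
    }
  }
  out
}
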