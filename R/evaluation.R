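#' Leave-one-out cross-validation of the assimilation
#'
#' Runs [optimal_interpolation()] once per observation with that
#' observation withheld, records the analysis at the held-out site, and
#' compares observed values against the background and against the
#' held-out analyses with [paired_metrics()]. Relative improvements are
#' `100 * (|metric_bg| - |metric_an|) / |metric_bg|` for MB, RMSE and MAE.
#' Reference stations take part exactly like sensors; summary metrics are
#' reported for all sites together and for the reference subset alone.
#'
#' @param x_b Background [aq_grid()].
#' @param obs Observation tibble (see [seasonal_observations()]), at least
#'   3 rows.
#' @param cfg An [oi_config()].
#' @return An object of class `aq_loocv`: `sites` (per held-out site:
#'   `observed`, `background`, `analysis`), `metrics` (background and
#'   analysis metric rows per site group) and `improvements` (per metric,
#'   percent; `NA`-flagged when the background metric is zero).
#' @export
loocv <- function(x_b, obs, cfg = oi_config()) {
  obs <- tibble::as_tibble(obs)
  n <- nrow(obs)
  if (n < 3) stop("loocv needs at least 3 observations", call. = FALSE)
  rows <- purrr::map(seq_len(n), function(i) {
    res <- tryCatch(
      optimal_interpolation(x_b, obs[-i, ], cfg),
      error = function(e) {
        stop(sprintf(
          "LOOCV failed when holding out site '%s': %s",
          obs$site_id[i], conditionMessage(e)
        ), call. = FALSE)
      }
    )
    ops <- build_operator(x_b, obs[i, ], cfg)
    vals_b <- as.vector(x_b$values)
    vals_a <- as.vector(res$analysis$values)
    tibble::tibble(
      site_id = obs$site_id[i],
      source = if ("source" %in% names(obs)) obs$source[i] else "lcs",
      observed = obs$value[i],
      background = sum(ops[[1]]$w * vals_b[ops[[1]]$idx]),
      analysis = sum(ops[[1]]$w * vals_a[ops[[1]]$idx])
    )
  })
  sites <- dplyr::bind_rows(rows)

  metric_rows <- function(d, group) {
    dplyr::bind_rows(
      paired_metrics(d, observed, background) |>
        dplyr::mutate(field = "background", group = group),
      paired_metrics(d, observed, analysis) |>
        dplyr::mutate(field = "analysis", group = group)
    )
  }
  metrics <- metric_rows(sites, "all")
  if (any(sites$source == "reference") && sum(sites$source == "reference") >= 2) {
    metrics <- dplyr::bind_rows(
      metrics,
      metric_rows(dplyr::filter(sites, .data$source == "reference"), "reference")
    )
  }
  improvement <- function(bg, an) {
    ifelse(abs(bg) > 0, 100 * (abs(bg) - abs(an)) / abs(bg), NA_real_)
  }
  imp <- metrics |>
    dplyr::select("group", "field", "mb", "rmse", "mae") |>
    tidyr::pivot_longer(c("mb", "rmse", "mae"), names_to = "metric") |>
    tidyr::pivot_wider(names_from = "field", values_from = "value") |>
    dplyr::mutate(improvement_pct = improvement(.data$background, .data$analysis))
  structure(
    list(sites = sites, metrics = metrics, improvements = imp, cfg = cfg),
    class = "aq_loocv"
  )
}

#' @export
print.aq_loocv <- function(x, ...) {
  cat(sprintf("<aq_loocv> %d held-out sites\n", nrow(x$sites)))
  print(dplyr::filter(x$improvements, .data$group == "all"))
  invisible(x)
}

#' Per-site LOOCV triples
#' @param x An `aq_loocv` from [loocv()].
#' @param ... Unused.
#' @return Tibble with one row per held-out site: `observed`,
#'   `background`, `analysis`.
#' @export
tidy.aq_loocv <- function(x, ...) x$sites

#' One-row LOOCV summary over all sites
#' @param x An `aq_loocv`.
#' @param ... Unused.
#' @return Tibble with background/analysis MB, RMSE, MAE and the relative
#'   improvements in percent.
#' @export
glance.aq_loocv <- function(x, ...) {
  w <- dplyr::filter(x$improvements, .data$group == "all")
  tibble::tibble(
    n = nrow(x$sites),
    mb_background = w$background[w$metric == "mb"],
    mb_analysis = w$analysis[w$metric == "mb"],
    rmse_background = w$background[w$metric == "rmse"],
    rmse_analysis = w$analysis[w$metric == "rmse"],
    mae_background = w$background[w$metric == "mae"],
    mae_analysis = w$analysis[w$metric == "mae"],
    mb_improvement_pct = w$improvement_pct[w$metric == "mb"],
    rmse_improvement_pct = w$improvement_pct[w$metric == "rmse"],
    mae_improvement_pct = w$improvement_pct[w$metric == "mae"]
  )
}

#' @export
autoplot.aq_loocv <- function(object, ...) {
  d <- object$sites |>
    tidyr::pivot_longer(c("background", "analysis"),
      names_to = "field", values_to = "predicted"
    )
  ggplot2::ggplot(d, ggplot2::aes(.data$observed, .data$predicted, color = .data$field)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = expression(Observed ~ PM[2.5] ~ (mu * g ~ m^-3)),
      y = expression(Predicted ~ PM[2.5] ~ (mu * g ~ m^-3))
    )
}

#' Mean diurnal cycle per group
#'
#' Mean PM2.5 over all records of each hour of day within each group
#' (neighborhood or individual station); groups with no data are omitted
#' with a warning.
#'
#' @param data A network tibble.
#' @param grouping `"neighborhood"` or `"station"` (per sensor id).
#' @return A tibble: `group`, `hour` (0-23), `mean_pm25`, `n`.
#' @export
diurnal_cycle <- function(data, grouping = c("neighborhood", "station")) {
  grouping <- match.arg(grouping)
  gvar <- if (grouping == "neighborhood") "neighborhood" else "sensor_id"
  empty <- data |>
    dplyr::group_by(group = .data[[gvar]]) |>
    dplyr::summarise(n = sum(!is.na(.data$pm25)), .groups = "drop") |>
    dplyr::filter(.data$n == 0)
  if (nrow(empty)) {
    warning(
      "group(s) without data omitted: ", paste(empty$group, collapse = ", "),
      call. = FALSE
    )
  }
  data |>
    dplyr::filter(!is.na(.data$pm25)) |>
    dplyr::mutate(hour = hour_of(.data$timestamp)) |>
    dplyr::group_by(group = .data[[gvar]], .data$hour) |>
    dplyr::summarise(mean_pm25 = mean(.data$pm25), n = dplyr::n(), .groups = "drop")
}

#' Neighborhood daily means with interquartile bands
#'
#' Per sensor and day, the daily mean is kept only when strictly more than
#' `min_day_coverage` of the 24 hours are present; per neighborhood and
#' day, the mean and interquartile range across member sensors' daily
#' means are returned.
#'
#' @param data A network tibble (sensors must carry neighborhood labels).
#' @param min_day_coverage Fraction of the day that must be present
#'   (default 0.75; days at or below it are dropped).
#' @return A tibble: `neighborhood`, `day`, `mean_pm25`, `q25`, `q75`,
#'   `n_sensors`.
#' @export
neighborhood_daily <- function(data, min_day_coverage = 0.75) {
  daily <- data |>
    dplyr::filter(.data$source == "lcs") |>
    dplyr::mutate(day = day_of(.data$timestamp)) |>
    dplyr::group_by(.data$sensor_id, .data$neighborhood, .data$day) |>
    dplyr::summarise(
      n_hours = sum(!is.na(.data$pm25)),
      daily_mean = mean(.data$pm25, na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n_hours / 24 > min_day_coverage)
  daily |>
    dplyr::group_by(.data$neighborhood, .data$day) |>
    dplyr::summarise(
      mean_pm25 = mean(.data$daily_mean),
      q25 = unname(stats::quantile(.data$daily_mean, 0.25, type = 7)),
      q75 = unname(stats::quantile(.data$daily_mean, 0.75, type = 7)),
      n_sensors = dplyr::n(),
      .groups = "drop"
    )
}

#' Plot neighborhood daily means with IQR ribbons
#' @param agg Output of [neighborhood_daily()].
#' @return A ggplot.
#' @export
plot_neighborhood_daily <- function(agg) {
  ggplot2::ggplot(agg, ggplot2::aes(.data$day, .data$mean_pm25)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$q25, ymax = .data$q75), alpha = 0.3) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~neighborhood) +
    ggplot2::labs(x = NULL, y = expression(Daily ~ PM[2.5] ~ (mu * g ~ m^-3)))
}

#' Plot diurnal cycles
#' @param cyc Output of [diurnal_cycle()].
#' @return A ggplot.
#' @export
plot_diurnal <- function(cyc) {
  ggplot2::ggplot(cyc, ggplot2::aes(.data$hour, .data$mean_pm25, color = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Hour of day", y = expression(Mean ~ PM[2.5] ~ (mu * g ~ m^-3)))
}
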