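#' Configuration for optimal interpolation
#'
#' @param sigma_b Background error standard deviation (ug/m3, default 2).
#' @param correlation_length Background error correlation length `Lc` (m,
#'   default 2000). With the Gaussian kernel, corrections decay as
#'   `exp(-d^2 / (2 Lc^2))` away from an observation.
#' @param kernel Correlation form: `"gaussian"` (`exp(-d^2/(2 Lc^2))`) or
#'   `"exponential"` (`exp(-d/Lc)`).
#' @param sd_reference,sd_lcs Default observation error standard deviations
#'   (ug/m3) by source type. The smaller reference value encodes the
#'   stronger weight given to the accurate reference measurements.
#' @param operator Observation operator: `"nearest"` samples the containing
#'   cell, `"bilinear"` interpolates the four surrounding cell centres.
#' @param coverage_threshold Minimum seasonal data coverage for a site to
#'   contribute an observation (default 0.75).
#' @param localization_radius Optional hard cutoff (m) beyond which
#'   background correlations are zeroed; `NULL` (default) disables it.
#' @return A list of class `oi_config`.
#' @export
oi_config <- function(sigma_b = 2, correlation_length = 2000,
                      kernel = c("gaussian", "exponential"),
                      sd_reference = 1, sd_lcs = 3,
                      operator = c("nearest", "bilinear"),
                      coverage_threshold = 0.75,
                      localization_radius = NULL) {
  kernel <- match.arg(kernel)
  operator <- match.arg(operator)
  stopifnot(
    sigma_b > 0, correlation_length > 0, sd_reference > 0, sd_lcs > 0,
    coverage_threshold > 0, coverage_threshold <= 1
  )
  structure(
    list(
      sigma_b = sigma_b, correlation_length = correlation_length,
      kernel = kernel, sd_reference = sd_reference, sd_lcs = sd_lcs,
      operator = operator, coverage_threshold = coverage_threshold,
      localization_radius = localization_radius
    ),
    class = "oi_config"
  )
}

oi_correlation <- function(d, cfg) {
  rho <- switch(cfg$kernel,
    gaussian = exp(-d^2 / (2 * cfg$correlation_length^2)),
    exponential = exp(-d / cfg$correlation_length)
  )
  if (!is.null(cfg$localization_radius)) rho[d > cfg$localization_radius] <- 0
  rho
}

#' Seasonal-mean point observations from a corrected network
#'
#' Averages each site's hourly PM2.5 over the season; sites whose data
#' coverage falls below the threshold are excluded (and listed in the
#' `excluded` attribute). Observation error standard deviations are
#' assigned by source type.
#'
#' @param data A QA-corrected network tibble.
#' @param season Length-2 POSIXct (or coercible) `[start, end)` window;
#'   default spans the data.
#' @param cfg An [oi_config()].
#' @return A tibble of observations: `site_id`, `easting`, `northing`,
#'   `value` (seasonal mean, ug/m3), `sd`, `var`, `source`, `coverage`,
#'   `n_hours`; attribute `excluded` lists under-covered sites.
#' @export
seasonal_observations <- function(data, season = NULL, cfg = oi_config()) {
  if (is.null(season)) {
    season <- c(min(data$timestamp), max(data$timestamp) + 3600)
  }
  season <- as.POSIXct(season, tz = "UTC")
  total_hours <- as.numeric(difftime(season[2], season[1], units = "hours"))
  if (total_hours <= 0) stop("empty season window", call. = FALSE)
  win <- data |>
    dplyr::filter(.data$timestamp >= season[1], .data$timestamp < season[2])
  if (nrow(win) == 0) stop("no records in the season window", call. = FALSE)
  sites <- win |>
    dplyr::group_by(.data$sensor_id) |>
    dplyr::summarise(
      easting = .data$easting[which.max(.data$timestamp)],
      northing = .data$northing[which.max(.data$timestamp)],
      source = .data$source[1],
      n_hours = sum(!is.na(.data$pm25)),
      value = mean(.data$pm25, na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      coverage = .data$n_hours / total_hours,
      sd = ifelse(.data$source == "reference", cfg$sd_reference, cfg$sd_lcs),
      var = .data$sd^2
    ) |>
    dplyr::rename(site_id = "sensor_id")
  keep <- sites$coverage >= cfg$coverage_threshold & is.finite(sites$value)
  excluded <- sites[!keep, ]
  if (nrow(excluded)) {
    message(
      "excluded ", nrow(excluded), " site(s) under ",
      round(100 * cfg$coverage_threshold), "% seasonal coverage: ",
      paste(excluded$site_id, collapse = ", ")
    )
  }
  obs <- sites[keep, c(
    "site_id", "easting", "northing", "value", "sd", "var",
    "source", "coverage", "n_hours"
  )]
  if (nrow(obs) == 0) stop("no site meets the seasonal coverage threshold", call. = FALSE)
  attr(obs, "excluded") <- excluded
  obs
}

# observation operator: per-observation support cells (linear index into
# the grid value vector, column-major over [row, col]) and weights
build_operator <- function(g, obs, cfg) {
  lin <- function(row, col) (col - 1L) * g$ny + row
  purrr::map(seq_len(nrow(obs)), function(i) {
    x <- obs$easting[i]
    y <- obs$northing[i]
    if (cfg$operator == "nearest") {
      cell <- grid_cell_of(g, x, y)
      list(idx = lin(cell[1, "row"], cell[1, "col"]), w = 1)
    } else {
      # bilinear in cell-centre coordinates, clamped at the domain edge
      fx <- (x - g$origin[1]) / g$cell_size - 0.5
      fy <- (y - g$origin[2]) / g$cell_size - 0.5
      c0 <- min(max(floor(fx) + 1, 1), g$nx - 1)
      r0 <- min(max(floor(fy) + 1, 1), g$ny - 1)
      tx <- min(max(fx - (c0 - 1), 0), 1)
      ty <- min(max(fy - (r0 - 1), 0), 1)
      list(
        idx = c(
          lin(r0, c0), lin(r0, c0 + 1),
          lin(r0 + 1, c0), lin(r0 + 1, c0 + 1)
        ),
        w = c(
          (1 - tx) * (1 - ty), tx * (1 - ty),
          (1 - tx) * ty, tx * ty
        )
      )
    }
  })
}

#' Optimal interpolation of point observations into a background field
#'
#' Computes the analysis `x_a = x_b + B H' (H B H' + R)^-1 (y - H x_b)`:
#' the background field is corrected by the observation-minus-background
#' innovations, weighted by the modelled background error covariance `B`
#' (variance `sigma_b^2` times an isotropic distance correlation) against
#' the diagonal observation error covariance `R`. The innovation system is
#' solved by Cholesky factorization. Observations sharing identical
#' coordinates are merged by inverse-variance weighting (with a warning)
#' to keep the system well conditioned.
#'
#' @param x_b Background [aq_grid()] (the a-priori model field).
#' @param obs Observation tibble as from [seasonal_observations()] (needs
#'   `site_id`, `easting`, `northing`, `value`, `var`; `source` optional).
#' @param cfg An [oi_config()].
#' @return An object of class `aq_oi`: `analysis` ([aq_grid()]),
#'   `background`, `sites` (per-site tibble with `background_at_site`,
#'   `innovation`, `analysis_at_site`) and `cfg`.
#' @examples
#' g <- aq_grid(matrix(10, 20, 20))
#' obs <- tibble::tibble(
#'   site_id = "s1", easting = 1050, northing = 950,
#'   value = 14, var = 4
#' )
#' oi <- optimal_interpolation(g, obs, oi_config(sigma_b = 2))
#' oi$sites$analysis_at_site
#' @export
optimal_interpolation <- function(x_b, obs, cfg = oi_config()) {
  stopifnot(inherits(x_b, "aq_grid"))
  obs <- tibble::as_tibble(obs)
  if (nrow(obs) == 0) stop("optimal_interpolation needs at least one observation", call. = FALSE)
  if (any(!is.finite(obs$value)) || any(!is.finite(obs$var)) || any(obs$var < 0)) {
    stop("observations need finite values and non-negative error variances", call. = FALSE)
  }
  dup <- duplicated(obs[, c("easting", "northing")])
  if (any(dup)) {
    warning("observations at identical coordinates merged by inverse-variance weighting",
      call. = FALSE
    )
    obs <- obs |>
      dplyr::group_by(.data$easting, .data$northing) |>
      dplyr::summarise(
        site_id = paste(.data$site_id, collapse = "+"),
        value = sum(.data$value / .data$var) / sum(1 / .data$var),
        var = 1 / sum(1 / .data$var),
        source = .data$source[1],
        .groups = "drop"
      ) |>
      dplyr::select("site_id", "easting", "northing", "value", "var", dplyr::any_of("source"))
  }
  p <- nrow(obs)
  vals <- as.vector(x_b$values)
  ops <- build_operator(x_b, obs, cfg)
  hx_b <- vapply(ops, function(o) {
    v <- vals[o$idx]
    if (any(!is.finite(v))) {
      stop("background field is missing at an observation site", call. = FALSE)
    }
    sum(o$w * v)
  }, 1)
  innovation <- obs$value - hx_b

  # cell-centre coordinates of every grid cell (column-major linear order)
  centres <- cbind(
    x_b$origin[1] + (rep(seq_len(x_b$nx), each = x_b$ny) - 0.5) * x_b$cell_size,
    x_b$origin[2] + (rep(seq_len(x_b$ny), times = x_b$nx) - 0.5) * x_b$cell_size
  )
  # B H': covariance between every grid cell and each observation support
  bht <- matrix(0, nrow(centres), p)
  for (j in seq_len(p)) {
    o <- ops[[j]]
    for (k in seq_along(o$idx)) {
      d <- sqrt((centres[, 1] - centres[o$idx[k], 1])^2 +
        (centres[, 2] - centres[o$idx[k], 2])^2)
      bht[, j] <- bht[, j] + o$w[k] * cfg$sigma_b^2 * oi_correlation(d, cfg)
    }
  }
  # H B H' from the same support cells
  hbht <- matrix(0, p, p)
  for (i in seq_len(p)) {
    o <- ops[[i]]
    hbht[i, ] <- colSums(o$w * matrix(bht[o$idx, ], nrow = length(o$idx)))
  }
  hbht <- (hbht + t(hbht)) / 2
  s_mat <- hbht + diag(obs$var, p)
  ch <- tryCatch(chol(s_mat), error = function(e) {
    stop(
      "innovation covariance is not positive definite; ",
      "increase observation error variances or merge duplicate sites",
      call. = FALSE
    )
  })
  alpha <- backsolve(ch, forwardsolve(t(ch), innovation))
  increment <- drop(bht %*% alpha)
  # OI is unconstrained: the analysis can dip (slightly) below zero where
  # negative innovations dominate, so non-negativity is not enforced here
  analysis <- aq_grid(
    matrix(vals + increment, x_b$ny, x_b$nx),
    origin = x_b$origin, cell_size = x_b$cell_size, check_nonneg = FALSE
  )
  analysis_vec <- as.vector(analysis$values)
  hx_a <- vapply(ops, function(o) sum(o$w * analysis_vec[o$idx]), 1)
  sites <- obs |>
    dplyr::mutate(
      background_at_site = hx_b,
      innovation = innovation,
      analysis_at_site = hx_a
    )
  structure(
    list(analysis = analysis, background = x_b, sites = sites, cfg = cfg),
    class = "aq_oi"
  )
}

#' @export
print.aq_oi <- function(x, ...) {
  cat(sprintf(
    "<aq_oi> %d observations; mean innovation %.3f, max |increment| %.3f ug/m3\n",
    nrow(x$sites), mean(x$sites$innovation),
    max(abs(x$analysis$values - x$background$values), na.rm = TRUE)
  ))
  invisible(x)
}

#' Innovation and increment diagnostics of an analysis
#'
#' @param result An `aq_oi` from [optimal_interpolation()].
#' @return A list: `sites` (per-site innovations and analysis values),
#'   `summary` (one-row tibble: `n`, `mean_innovation`, `sd_innovation`)
#'   and `increment` (analysis-minus-background [aq_grid()]).
#' @export
innovation_stats <- function(result) {
  stopifnot(inherits(result, "aq_oi"))
  inc <- result$analysis$values - result$background$values
  list(
    sites = result$sites,
    summary = tibble::tibble(
      n = nrow(result$sites),
      mean_innovation = mean(result$sites$innovation),
      sd_innovation = stats::sd(result$sites$innovation)
    ),
    increment = aq_grid(inc,
      origin = result$background$origin,
      cell_size = result$background$cell_size, check_nonneg = FALSE
    )
  )
}

#' Tidy per-site assimilation results
#' @param x An `aq_oi` object.
#' @param ... Unused.
#' @return The per-site tibble with background, innovation and analysis.
#' @export
tidy.aq_oi <- function(x, ...) x$sites

#' One-row summary of an assimilation
#' @param x An `aq_oi` object.
#' @param ... Unused.
#' @return Tibble: observation count, mean/sd innovation, max |increment|.
#' @export
glance.aq_oi <- function(x, ...) {
  tibble::tibble(
    n_obs = nrow(x$sites),
    mean_innovation = mean(x$sites$innovation),
    sd_innovation = stats::sd(x$sites$innovation),
    max_abs_increment = max(abs(x$analysis$values - x$background$values), na.rm = TRUE)
  )
}

#' @export
autoplot.aq_oi <- function(object, ...) {
  autoplot.aq_grid(object$analysis) +
    ggplot2::geom_point(
      data = object$sites,
      ggplot2::aes(.data$easting, .data$northing, fill = .data$value),
      shape = 21, size = 3, color = "black"
    ) +
    ggplot2::labs(title = "Analysis field with observations")
}
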