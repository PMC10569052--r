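#' Configuration for the synthetic winter deployment
#'
#' Defines the conditions the generator emulates: a smooth correlated urban
#' background with a localized residential wood-combustion hotspot in a
#' valley neighborhood, an a-priori model field that underestimates that
#' hotspot, a network of low-cost sensors with multiplicative gain error,
#' weekly-varying additive offsets, RH-dependent noise, optional linear
#' drift, gaps and relocations, and two low-noise reference stations.
#'
#' Defaults describe a 4 x 4 km domain at 100 m resolution over a 90-day
#' winter: seasonal background 8 ug/m3, hotspot amplitude 6 ug/m3 of which
#' the model misses 70% (a model deficit of ~4.2 ug/m3 at the hotspot
#' core), 25 sensors of which 8 cluster in the hotspot neighborhood, and a
#' mean sensor gain of 1/0.49 (the factory calibration overestimates mass
#' by about a factor two in winter conditions).
#'
#' @param nx,ny,cell_size Grid dimensions (cells) and cell edge (m).
#' @param background_mean,background_sd Seasonal-mean background level and
#'   spatial standard deviation (ug/m3).
#' @param correlation_length Spatial correlation length of the smooth
#'   background (m).
#' @param hotspot_center,hotspot_radius,hotspot_amplitude Gaussian hotspot:
#'   centre (m), e-folding radius (m) and peak amplitude (ug/m3).
#' @param model_bias Fraction of the hotspot the a-priori model field
#'   misses (0 = perfect model, 1 = hotspot absent from the model).
#' @param model_error_sd Spatial sd of the smooth model-error field added
#'   to the a-priori field (ug/m3).
#' @param n_sensors,n_hotspot_sensors Total LCS count and how many of them
#'   cluster inside the hotspot neighborhood.
#' @param gain_mean,gain_sd Multiplicative sensor gain distribution
#'   (dimensionless; mean 1/0.49 by default).
#' @param weekly_offset_sd Sd of the per-sensor per-ISO-week additive
#'   offset (ug/m3).
#' @param noise_sd Baseline sd of the per-record Gaussian noise (ug/m3);
#'   inflated by humidity as `noise_sd * (1 + rh_coeff * max(0, RH - 70)/30)`.
#' @param rh_coeff Humidity coupling coefficient of the noise model.
#' @param drift_slopes Named numeric vector of linear drifts (ug/m3 per
#'   day) keyed by sensor id, e.g. `c(lcs_03 = 0.05)`. Default: none.
#' @param missingness Per-record missingness probability in `[0, 1)`.
#' @param relocations Optional tibble `(sensor_id, day)`: each listed
#'   sensor moves to a new random location at 00:00 of `day` (1-based day
#'   of season) and receives a registry entry. Default: none.
#' @param season_start Date of the first day (local standard time).
#' @param n_days Season length in days (default 90, one winter).
#' @param diurnal_peaks,diurnal_sds,diurnal_strength Bimodal diurnal
#'   profile: peak hours (default 10:00 and 19:00, the observed morning and
#'   evening maxima), Gaussian widths (h) and the share of the profile
#'   carried by the peaks (0 = flat).
#' @param daily_sdlog Sd (log scale) of the day-to-day lognormal factor
#'   shared across the domain (synoptic variability).
#' @param hourly_sdlog,hourly_ar Sd (log scale) and lag-1 autocorrelation
#'   of the hour-to-hour lognormal factor shared across the domain
#'   (city-wide sub-daily fluctuation; this shared variability is what the
#'   blind network correlation screen relies on).
#' @param ref_noise_sd Reference-station noise sd (ug/m3).
#' @param corrupt_sensors Character vector of sensor ids whose output is
#'   replaced by independent noise uncorrelated with the network (used to
#'   exercise the correlation screen). Default: none.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(nx = 40, ny = 40, cell_size = 100,
                         background_mean = 8, background_sd = 1.5,
                         correlation_length = 1000,
                         hotspot_center = c(1200, 2800), hotspot_radius = 600,
                         hotspot_amplitude = 6,
                         model_bias = 0.7, model_error_sd = 0.5,
                         n_sensors = 25, n_hotspot_sensors = 8,
                         gain_mean = 1 / 0.49, gain_sd = 0.08,
                         weekly_offset_sd = 0.75,
                         noise_sd = 1, rh_coeff = 0.5,
                         drift_slopes = NULL,
                         missingness = 0.05,
                         relocations = NULL,
                         season_start = "2020-12-01", n_days = 90,
                         diurnal_peaks = c(10, 19), diurnal_sds = c(2.5, 3.5),
                         diurnal_strength = 0.4,
                         daily_sdlog = 0.4,
                         hourly_sdlog = 0.3, hourly_ar = 0.9,
                         ref_noise_sd = 0.5,
                         corrupt_sensors = NULL) {
  cfg <- list(
    nx = nx, ny = ny, cell_size = cell_size,
    background_mean = background_mean, background_sd = background_sd,
    correlation_length = correlation_length,
    hotspot_center = hotspot_center, hotspot_radius = hotspot_radius,
    hotspot_amplitude = hotspot_amplitude,
    model_bias = model_bias, model_error_sd = model_error_sd,
    n_sensors = n_sensors, n_hotspot_sensors = n_hotspot_sensors,
    gain_mean = gain_mean, gain_sd = gain_sd,
    weekly_offset_sd = weekly_offset_sd,
    noise_sd = noise_sd, rh_coeff = rh_coeff,
    drift_slopes = drift_slopes,
    missingness = missingness,
    relocations = relocations,
    season_start = season_start, n_days = n_days,
    diurnal_peaks = diurnal_peaks, diurnal_sds = diurnal_sds,
    diurnal_strength = diurnal_strength,
    daily_sdlog = daily_sdlog,
    hourly_sdlog = hourly_sdlog, hourly_ar = hourly_ar,
    ref_noise_sd = ref_noise_sd,
    corrupt_sensors = corrupt_sensors
  )
  scales <- c(
    cell_size = cell_size, correlation_length = correlation_length,
    hotspot_radius = hotspot_radius, n_days = n_days
  )
  if (any(scales <= 0)) stop("all synthetic scales must be > 0", call. = FALSE)
  if (missingness < 0 || missingness >= 1) stop("missingness must be in [0, 1)", call. = FALSE)
  hx <- hotspot_center[1]
  hy <- hotspot_center[2]
  if (hx < 0 || hx > nx * cell_size || hy < 0 || hy > ny * cell_size) {
    stop("hotspot centre lies outside the domain", call. = FALSE)
  }
  if (n_hotspot_sensors > n_sensors) {
    stop("n_hotspot_sensors cannot exceed n_sensors", call. = FALSE)
  }
  if (!is.null(drift_slopes) && length(drift_slopes) > n_sensors) {
    stop("more drifting sensors than sensors", call. = FALSE)
  }
  structure(cfg, class = "synth_config")
}

# separable Gaussian smoothing of a matrix, kernel renormalised at edges
smooth_gaussian <- function(m, sigma_cells) {
  smooth_1d <- function(nn) {
    half <- max(1L, ceiling(3 * sigma_cells))
    k <- stats::dnorm(-half:half, sd = sigma_cells)
    W <- matrix(0, nn, nn)
    for (i in seq_len(nn)) {
      idx <- (i - half):(i + half)
      keep <- idx >= 1 & idx <= nn
      W[i, idx[keep]] <- k[keep] / sum(k[keep])
    }
    W
  }
  Wr <- smooth_1d(nrow(m))
  Wc <- smooth_1d(ncol(m))
  Wr %*% m %*% t(Wc)
}

# correlated zero-mean field with unit variance on the cfg grid
correlated_field <- function(cfg) {
  sigma_cells <- cfg$correlation_length / cfg$cell_size
  f <- smooth_gaussian(matrix(stats::rnorm(cfg$ny * cfg$nx), cfg$ny, cfg$nx), sigma_cells)
  (f - mean(f)) / stats::sd(as.vector(f))
}

hotspot_field <- function(cfg) {
  cx <- seq_len(cfg$nx) - 0.5
  cy <- seq_len(cfg$ny) - 0.5
  ex <- cx * cfg$cell_size
  ny_ <- cy * cfg$cell_size
  d2 <- outer(ny_, ex, function(y, x) {
    (x - cfg$hotspot_center[1])^2 + (y - cfg$hotspot_center[2])^2
  })
  cfg$hotspot_amplitude * exp(-d2 / (2 * cfg$hotspot_radius^2))
}

# normalised bimodal diurnal weight, mean 1 over the 24 hours
diurnal_profile <- function(cfg) {
  h <- 0:23
  g <- exp(-(h - cfg$diurnal_peaks[1])^2 / (2 * cfg$diurnal_sds[1]^2)) +
    0.8 * exp(-(h - cfg$diurnal_peaks[2])^2 / (2 * cfg$diurnal_sds[2]^2))
  (1 - cfg$diurnal_strength) + cfg$diurnal_strength * g / mean(g)
}

#' Generate the ground-truth and a-priori fields
#'
#' The seasonal truth field is a smooth spatially correlated background
#' plus a radially decaying hotspot; the a-priori (model) field reproduces
#' the background but misses a configured fraction of the hotspot, plus its
#' own smooth error field. Hourly truth at a point is the seasonal value
#' modulated by the normalised bimodal diurnal profile and a day-to-day
#' lognormal factor shared across the domain.
#'
#' @param cfg A [synth_config()].
#' @param seed Integer seed; the same `(cfg, seed)` always reproduces the
#'   same bundle bit for bit.
#' @return An object of class `aq_truth`: `truth_field` and `model_field`
#'   ([aq_grid()]s), `diurnal` (24 weights, mean 1), `day_factors`
#'   (length `n_days`), `timestamps` (hourly POSIXct) and `cfg`.
#' @export
generate_truth <- function(cfg, seed) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(seed)
  bg <- cfg$background_mean + cfg$background_sd * correlated_field(cfg)
  hs <- hotspot_field(cfg)
  truth <- pmax(bg + hs, 0)
  model <- pmax(bg + (1 - cfg$model_bias) * hs +
    cfg$model_error_sd * correlated_field(cfg), 0)
  t0 <- as.POSIXct(paste(cfg$season_start, "00:00:00"), tz = "UTC")
  timestamps <- t0 + 3600 * (0:(cfg$n_days * 24 - 1))
  day_factors <- stats::rlnorm(cfg$n_days,
    meanlog = -cfg$daily_sdlog^2 / 2, sdlog = cfg$daily_sdlog
  )
  # shared hour-to-hour AR(1) lognormal factor, stationary sd = hourly_sdlog
  n_t <- length(timestamps)
  z <- numeric(n_t)
  innov <- stats::rnorm(n_t, 0, cfg$hourly_sdlog)
  z[1] <- innov[1]
  if (n_t > 1) {
    scale <- sqrt(1 - cfg$hourly_ar^2)
    for (t in 2:n_t) z[t] <- cfg$hourly_ar * z[t - 1] + scale * innov[t]
  }
  hour_factors <- exp(z - cfg$hourly_sdlog^2 / 2)
  structure(
    list(
      truth_field = aq_grid(truth, origin = c(0, 0), cell_size = cfg$cell_size),
      model_field = aq_grid(model, origin = c(0, 0), cell_size = cfg$cell_size),
      diurnal = diurnal_profile(cfg),
      day_factors = day_factors,
      hour_factors = hour_factors,
      timestamps = timestamps,
      cfg = cfg
    ),
    class = "aq_truth"
  )
}

#' Hourly truth series at a point
#'
#' @param bundle An `aq_truth` from [generate_truth()].
#' @param easting,northing Query point (m); the seasonal value of the
#'   containing grid cell is used.
#' @return A tibble `(timestamp, pm25)` covering the season.
#' @export
truth_series <- function(bundle, easting, northing) {
  cell <- grid_cell_of(bundle$truth_field, easting, northing)
  seasonal <- bundle$truth_field$values[cell[1, "row"], cell[1, "col"]]
  ts <- bundle$timestamps
  h <- hour_of(ts)
  d <- rep(seq_len(bundle$cfg$n_days), each = 24)
  tibble::tibble(
    timestamp = ts,
    pm25 = seasonal * bundle$diurnal[h + 1] * bundle$day_factors[d] *
      bundle$hour_factors
  )
}

#' Generate the synthetic sensor network
#'
#' Places `n_hotspot_sensors` inside the hotspot neighborhood and the rest
#' across the remaining domain, assigns each a gain, weekly offsets and
#' RH-dependent noise, applies optional drift, corruption, gaps and
#' relocations, and adds two low-noise reference stations (an urban
#' background station nearer the network and a traffic station further
#' away, both outside the hotspot).
#'
#' @param bundle An `aq_truth` from [generate_truth()].
#' @param cfg The same [synth_config()] used for the bundle.
#' @param seed Integer seed.
#' @return A network tibble (see [read_network()]) with the relocation
#'   registry attached, plus a `sensor_truth` attribute mapping each
#'   sensor to its gain and true seasonal level (ground truth for tests).
#' @export
generate_network <- function(bundle, cfg, seed) {
  stopifnot(inherits(bundle, "aq_truth"), inherits(cfg, "synth_config"))
  set.seed(seed)
  g <- bundle$truth_field
  width <- cfg$nx * cfg$cell_size
  height <- cfg$ny * cfg$cell_size
  if (cfg$n_sensors > cfg$nx * cfg$ny) stop("more sensors than grid cells", call. = FALSE)

  ids <- sprintf("lcs_%02d", seq_len(cfg$n_sensors))
  in_disk <- function(n, center, radius) {
    ang <- stats::runif(n, 0, 2 * pi)
    rad <- radius * sqrt(stats::runif(n))
    cbind(center[1] + rad * cos(ang), center[2] + rad * sin(ang))
  }
  clamp <- function(xy) {
    cbind(
      pmin(pmax(xy[, 1], cfg$cell_size / 2), width - cfg$cell_size / 2),
      pmin(pmax(xy[, 2], cfg$cell_size / 2), height - cfg$cell_size / 2)
    )
  }
  n_out <- cfg$n_sensors - cfg$n_hotspot_sensors
  loc_hot <- clamp(in_disk(cfg$n_hotspot_sensors, cfg$hotspot_center, cfg$hotspot_radius))
  loc_out <- matrix(numeric(0), 0, 2)
  while (nrow(loc_out) < n_out) {
    cand <- cbind(stats::runif(n_out, 0, width), stats::runif(n_out, 0, height))
    far <- sqrt((cand[, 1] - cfg$hotspot_center[1])^2 +
      (cand[, 2] - cfg$hotspot_center[2])^2) > 1.5 * cfg$hotspot_radius
    loc_out <- rbind(loc_out, clamp(cand[far, , drop = FALSE]))
  }
  loc_out <- loc_out[seq_len(n_out), , drop = FALSE]
  locs <- rbind(loc_hot, loc_out)

  neigh_of <- function(x, y) {
    d_hot <- sqrt((x - cfg$hotspot_center[1])^2 + (y - cfg$hotspot_center[2])^2)
    dplyr::case_when(
      d_hot <= 1.5 * cfg$hotspot_radius ~ "Grim",
      x < width / 2 ~ "Kvadraturen",
      TRUE ~ "Lund"
    )
  }

  gains <- stats::rnorm(cfg$n_sensors, cfg$gain_mean, cfg$gain_sd)
  gains <- pmax(gains, 0.1)
  names(gains) <- ids

  ts <- bundle$timestamps
  n_t <- length(ts)
  h <- hour_of(ts)
  d <- rep(seq_len(cfg$n_days), each = 24)
  elapsed_days <- as.numeric(difftime(ts, ts[1], units = "days"))
  weeks <- iso_week_of(ts)
  uweeks <- unique(weeks)

  # shared hourly RH: diurnal sinusoid around 80%, mostly above 70%
  rh <- 80 + 8 * sin(2 * pi * (h - 16) / 24) + stats::rnorm(n_t, 0, 4)
  rh <- pmin(pmax(rh, 30), 100)
  temp <- -1 + 4 * sin(2 * pi * (h - 15) / 24) + stats::rnorm(n_t, 0, 2)

  seasonal_at <- function(x, y) {
    cell <- grid_cell_of(g, x, y)
    g$values[cell[1, "row"], cell[1, "col"]]
  }

  reloc_tbl <- cfg$relocations
  registry_rows <- list()
  sensor_rows <- vector("list", cfg$n_sensors)
  truth_rows <- vector("list", cfg$n_sensors)

  for (i in seq_len(cfg$n_sensors)) {
    id <- ids[i]
    x <- locs[i, 1]
    y <- locs[i, 2]
    seasonal <- seasonal_at(x, y)
    truth_i <- seasonal * bundle$diurnal[h + 1] * bundle$day_factors[d] *
      bundle$hour_factors
    east_i <- rep(x, n_t)
    north_i <- rep(y, n_t)
    neigh_i <- rep(neigh_of(x, y), n_t)

    if (!is.null(reloc_tbl) && id %in% reloc_tbl$sensor_id) {
      day_move <- reloc_tbl$day[match(id, reloc_tbl$sensor_id)]
      t_move <- ts[1] + (day_move - 1) * 86400
      new_xy <- clamp(cbind(stats::runif(1, 0, width), stats::runif(1, 0, height)))
      moved <- ts >= t_move
      east_i[moved] <- new_xy[1]
      north_i[moved] <- new_xy[2]
      neigh_i[moved] <- neigh_of(new_xy[1], new_xy[2])
      seasonal2 <- seasonal_at(new_xy[1], new_xy[2])
      truth_i[moved] <- seasonal2 * bundle$diurnal[h[moved] + 1] *
        bundle$day_factors[d[moved]] * bundle$hour_factors[moved]
      registry_rows[[length(registry_rows) + 1]] <-
        tibble::tibble(sensor_id = id, relocated_at = t_move)
    }

    offsets <- stats::rnorm(length(uweeks), 0, cfg$weekly_offset_sd)
    names(offsets) <- uweeks
    noise_scale <- cfg$noise_sd * (1 + cfg$rh_coeff * pmax(0, rh - 70) / 30)
    eps <- stats::rnorm(n_t, 0, 1) * noise_scale
    pm <- gains[id] * truth_i + unname(offsets[weeks]) + eps
    if (!is.null(cfg$drift_slopes) && id %in% names(cfg$drift_slopes)) {
      pm <- pm + cfg$drift_slopes[[id]] * elapsed_days
    }
    if (!is.null(cfg$corrupt_sensors) && id %in% cfg$corrupt_sensors) {
      pm <- cfg$gain_mean * cfg$background_mean *
        stats::rlnorm(n_t, meanlog = -0.125, sdlog = 0.5)
    }
    pm <- pmax(pm, 0)
    if (cfg$missingness > 0) {
      pm[stats::runif(n_t) < cfg$missingness] <- NA_real_
    }
    sensor_rows[[i]] <- tibble::tibble(
      sensor_id = id, timestamp = ts, pm25 = pm, rh = rh, temp = temp,
      easting = east_i, northing = north_i, neighborhood = neigh_i,
      source = "lcs"
    )
    truth_rows[[i]] <- tibble::tibble(
      sensor_id = id, easting = x, northing = y,
      gain = unname(gains[id]), seasonal_truth = seasonal
    )
  }

  refs <- tibble::tibble(
    sensor_id = c("ref_background", "ref_traffic"),
    role = c("background", "traffic"),
    easting = c(0.6 * width, 0.85 * width),
    northing = c(0.55 * height, 0.2 * height),
    neighborhood = c("Kvadraturen", "Lund")
  )
  ref_rows <- purrr::pmap(refs, function(sensor_id, role, easting, northing, neighborhood) {
    seasonal <- seasonal_at(easting, northing)
    truth_i <- seasonal * bundle$diurnal[h + 1] * bundle$day_factors[d] *
      bundle$hour_factors
    tibble::tibble(
      sensor_id = sensor_id, timestamp = ts,
      pm25 = pmax(truth_i + stats::rnorm(n_t, 0, cfg$ref_noise_sd), 0),
      rh = rh, temp = temp,
      easting = easting, northing = northing,
      neighborhood = neighborhood, source = "reference"
    )
  })

  data <- dplyr::bind_rows(c(sensor_rows, ref_rows))
  registry <- if (length(registry_rows)) dplyr::bind_rows(registry_rows) else NULL
  out <- as_network(data, registry = registry)
  attr(out, "sensor_truth") <- dplyr::bind_rows(truth_rows)
  out
}

#' Generate a full synthetic deployment
#'
#' Convenience wrapper: truth bundle plus network from one seed.
#'
#' @inheritParams generate_truth
#' @return A list with `truth` (the `aq_truth` bundle) and `network` (the
#'   hourly tibble).
#' @export
simulate_network <- function(cfg = synth_config(), seed = 1) {
  bundle <- generate_truth(cfg, seed)
  list(truth = bundle, network = generate_network(bundle, cfg, seed + 500000L))
}

#' Generate a synthetic daily colocation series
#'
#' Daily-averaged reference concentrations with a colocated sensor whose
#' output is `gain * reference + noise`, for exercising the robust
#' calibration fit.
#'
#' @param n_days Number of daily pairs (default 28, two fortnights).
#' @param gain True multiplicative sensor gain (default 1/0.49).
#' @param noise_sd Sd of the daily sensor noise (ug/m3).
#' @param ref_mean,ref_sdlog Lognormal parameters of the daily reference
#'   concentrations (median `ref_mean` ug/m3).
#' @param seed Integer seed.
#' @return A tibble `(day, ref, sensor)`.
#' @export
generate_colocation <- function(n_days = 28, gain = 1 / 0.49, noise_sd = 2,
                                ref_mean = 10, ref_sdlog = 0.5, seed = 1) {
  set.seed(seed)
  ref <- stats::rlnorm(n_days, meanlog = log(ref_mean), sdlog = ref_sdlog)
  sensor <- pmax(gain * ref + stats::rnorm(n_days, 0, noise_sd), 0)
  tibble::tibble(day = seq_len(n_days), ref = ref, sensor = sensor)
}
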