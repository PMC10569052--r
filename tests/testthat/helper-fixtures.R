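# small in-code fixtures shared across test files

# hourly timestamps starting at local-standard midnight
hourly_ts <- function(n, start = "2021-01-01") {
  as.POSIXct(paste(start, "00:00:00"), tz = "UTC") + 3600 * (0:(n - 1))
}

# a minimal valid network tibble: one or more sensors with constant or
# supplied pm25 series, plus an optional reference station
tiny_network <- function(n_hours = 48, sensors = c("s1", "s2"),
                         pm25 = NULL, ref = FALSE, start = "2021-01-01") {
  ts <- hourly_ts(n_hours, start)
  rows <- lapply(seq_along(sensors), function(i) {
    tibble::tibble(
      sensor_id = sensors[i], timestamp = ts,
      pm25 = if (is.null(pm25)) rep(5 + i, n_hours) else pm25[[i]],
      rh = 80, temp = 0,
      easting = 500 * i, northing = 700 * i,
      neighborhood = "Grim", source = "lcs"
    )
  })
  if (ref) {
    rows <- c(rows, list(tibble::tibble(
      sensor_id = "ref_background", timestamp = ts,
      pm25 = rep(6, n_hours), rh = 80, temp = 0,
      easting = 2000, northing = 2000,
      neighborhood = "Kvadraturen", source = "reference"
    )))
  }
  as_network(dplyr::bind_rows(rows))
}

# small fast synthetic configuration for pipeline tests (2 x 2 km domain)
small_cfg <- function(...) {
  args <- utils::modifyList(
    list(
      nx = 20, ny = 20, n_sensors = 8, n_hotspot_sensors = 3,
      hotspot_center = c(600, 1400), hotspot_radius = 400,
      n_days = 62, missingness = 0 # Dec + Jan: whole calendar months
    ),
    list(...)
  )
  do.call(synth_config, args)
}
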