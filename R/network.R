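#' Read a long-format sensor network CSV
#'
#' The network is kept as a long tibble: one row per sensor per hour, with
#' the sensor's deployment metadata repeated on each row. Reference-station
#' records live in the same tibble, distinguished by `source = "reference"`;
#' this keeps every downstream verb a plain dplyr pipeline.
#'
#' Malformed values are never silently dropped: physically impossible
#' readings (PM2.5 below zero, relative humidity outside 0-100) are set to
#' missing and counted in the `parse_log` attribute, and a warning reports
#' the totals. Structural problems (a missing mandatory column, timestamps
#' that are not strictly increasing within a sensor) are errors.
#'
#' @param path Path to a CSV with header columns `sensor_id`, `timestamp`
#'   (ISO-8601, hour-beginning local standard time), `pm25`, `rh`, `temp`,
#'   `easting`, `northing`, `neighborhood` and optionally `source`
#'   (`"lcs"` or `"reference"`, default `"lcs"`).
#' @param registry_path Optional path to a relocation registry CSV with
#'   columns `sensor_id`, `relocated_at`; attached as the `registry`
#'   attribute of the result.
#'
#' @return A tibble of hourly records, timestamps as POSIXct (UTC-encoded
#'   local standard time), with attributes `registry` (tibble or NULL) and
#'   `parse_log` (tibble of issue counts).
#' @export
read_network <- function(path, registry_path = NULL) {
  mandatory <- c(
    "sensor_id", "timestamp", "pm25", "rh", "temp",
    "easting", "northing", "neighborhood"
  )
  header <- names(readr::read_csv(path,
    n_max = 0, show_col_types = FALSE,
    progress = FALSE
  ))
  missing_cols <- setdiff(mandatory, header)
  if (length(missing_cols)) {
    stop(
      "network CSV is missing mandatory column(s): ",
      paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(
      sensor_id = readr::col_character(),
      timestamp = readr::col_datetime(),
      pm25 = readr::col_double(),
      rh = readr::col_double(),
      temp = readr::col_double(),
      easting = readr::col_double(),
      northing = readr::col_double(),
      neighborhood = readr::col_character(),
      .default = readr::col_character()
    ),
    locale = readr::locale(tz = "UTC"),
    progress = FALSE
  )
  if (!"source" %in% names(raw)) raw$source <- "lcs"
  registry <- if (!is.null(registry_path)) read_registry(registry_path) else NULL
  as_network(raw, registry = registry)
}

#' Coerce and validate a network tibble
#'
#' Applies the in-memory contract of the hourly network table: invalidates
#' impossible readings (counted, warned about), checks that timestamps are
#' strictly increasing within each sensor, and attaches the registry.
#'
#' @param data A data frame with the columns documented in [read_network()].
#' @param registry Optional relocation registry tibble
#'   (`sensor_id`, `relocated_at`).
#' @return The validated tibble with `registry` and `parse_log` attributes.
#' @export
as_network <- function(data, registry = NULL) {
  data <- tibble::as_tibble(data)
  if (!"source" %in% names(data)) data$source <- "lcs"
  log <- tibble::tibble(issue = character(), n = integer())
  bad_pm <- !is.na(data$pm25) & data$pm25 < 0
  if (any(bad_pm)) {
    data$pm25[bad_pm] <- NA_real_
    log <- dplyr::bind_rows(log, tibble::tibble(issue = "negative pm25 set missing", n = sum(bad_pm)))
  }
  bad_rh <- !is.na(data$rh) & (data$rh < 0 | data$rh > 100)
  if (any(bad_rh)) {
    data$rh[bad_rh] <- NA_real_
    log <- dplyr::bind_rows(log, tibble::tibble(issue = "rh outside [0, 100] set missing", n = sum(bad_rh)))
  }
  if (nrow(log)) {
    warning(
      sprintf("%d malformed value(s) set to missing; see attr(x, 'parse_log')", sum(log$n)),
      call. = FALSE
    )
  }
  non_mono <- data |>
    dplyr::group_by(.data$sensor_id) |>
    dplyr::summarise(ok = !is.unsorted(.data$timestamp, strictly = TRUE), .groups = "drop") |>
    dplyr::filter(!.data$ok)
  if (nrow(non_mono)) {
    stop(
      "non-monotone timestamps for sensor(s): ",
      paste(non_mono$sensor_id, collapse = ", "),
      call. = FALSE
    )
  }
  if (!is.null(registry)) {
    if (anyDuplicated(registry$sensor_id)) {
      stop("relocation registry has more than one entry for a sensor", call. = FALSE)
    }
  }
  attr(data, "registry") <- registry
  attr(data, "parse_log") <- log
  data
}

#' @rdname read_network
#' @param data A network tibble.
#' @export
write_network <- function(data, path) {
  cols <- c(
    "sensor_id", "timestamp", "pm25", "rh", "temp",
    "easting", "northing", "neighborhood", "source"
  )
  readr::write_csv(dplyr::select(data, dplyr::all_of(cols)), path, progress = FALSE)
  invisible(path)
}

#' Read or write a sensor relocation registry
#'
#' @param path CSV with columns `sensor_id`, `relocated_at` (ISO-8601).
#' @return A tibble with one row per relocated sensor.
#' @export
read_registry <- function(path) {
  reg <- readr::read_csv(
    path,
    col_types = readr::cols(
      sensor_id = readr::col_character(),
      relocated_at = readr::col_datetime()
    ),
    locale = readr::locale(tz = "UTC"),
    progress = FALSE
  )
  if (!all(c("sensor_id", "relocated_at") %in% names(reg))) {
    stop("registry CSV needs columns sensor_id, relocated_at", call. = FALSE)
  }
  if (anyDuplicated(reg$sensor_id)) {
    stop("relocation registry has more than one entry for a sensor", call. = FALSE)
  }
  reg
}

#' @rdname read_registry
#' @param registry Registry tibble.
#' @export
write_registry <- function(registry, path) {
  readr::write_csv(registry, path, progress = FALSE)
  invisible(path)
}

#' Fetch the relocation registry attached to a network tibble
#' @param data A network tibble from [read_network()] / [as_network()].
#' @return The registry tibble, or an empty registry if none is attached.
#' @export
network_registry <- function(data) {
  reg <- attr(data, "registry")
  if (is.null(reg)) {
    tibble::tibble(
      sensor_id = character(),
      relocated_at = as.POSIXct(character(), tz = "UTC")
    )
  } else {
    reg
  }
}

# hour-of-day, calendar month and day helpers; all timestamps are
# hour-beginning local standard time carried in UTC, so no DST arithmetic
hour_of <- function(ts) as.integer(format(ts, "%H", tz = "UTC"))
month_of <- function(ts) format(ts, "%Y-%m", tz = "UTC")
day_of <- function(ts) as.Date(ts, tz = "UTC")
iso_week_of <- function(ts) format(ts, "%G-W%V", tz = "UTC")

is_night <- function(ts, window = c(0L, 5L)) {
  h <- hour_of(ts)
  h >= window[1] & h < window[2]
}
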