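#' Configuration for the five-step network quality assurance scheme
#'
#' @param night_window Integer pair: half-open hour-of-day window used for
#'   the correlation screen and drift baseline (default `c(0, 5)`, i.e.
#'   00:00-04:59 local standard time, when local emissions are minimal).
#' @param min_month_hours Minimum non-missing hours a sensor needs in a
#'   calendar month to keep that month (default 365, about half a month;
#'   the effective threshold is `min(min_month_hours, 0.5 * hours in
#'   month)` and the comparison is strict less-than).
#' @param corr_threshold Fixed screening threshold on the nighttime
#'   sensor-versus-network-mean Pearson r (default 0.7; a sensor-month
#'   whose r is at or below the threshold is removed).
#' @param corr_mode `"fixed"` uses `corr_threshold`; `"mu3sigma"` removes
#'   sensor-months with r below the month's mean minus three standard
#'   deviations of all sensors' r values.
#' @param exclude_self If `TRUE` the network mean excludes the sensor under
#'   test (default `FALSE`: the mean is over all sensors' measurements).
#' @param min_screen_pairs Minimum paired night hours for a screening r to
#'   be acted on (default 25, about five nights); below this the
#'   sensor-month is kept but flagged `insufficient-for-screening`.
#' @param gain Multiplicative correction factor applied to every sensor
#'   PM2.5 value in step 4 (default 0.49, the factory-output gain
#'   correction estimated by colocation).
#' @param offset_reference Station id used for the weekly offset
#'   adjustment (default `"ref_background"`, the urban background station).
#' @param min_offset_pairs Minimum paired hours in an ISO week for the
#'   weekly offset to be applied (default 24); sparser weeks are left
#'   uncorrected and flagged.
#' @param drift List of drift-assessment settings: `min_run_days` (default
#'   90: a sensor needs at least this many consecutive days of nightly
#'   bias to be assessed), `ssa_window` (SSA window length in days, `NULL`
#'   for the [ssa_decompose()] default), `alpha` (slope-test level, 0.05),
#'   `fit_target` (`"raw"` fits the regression to the raw nightly bias;
#'   `"ssa-trend"` fits the SSA trend component, anticonservative and
#'   flagged as such), `min_night_hours` (paired night hours needed for a
#'   valid nightly bias, default 3).
#' @return A list of class `qa_config`.
#' @export
qa_config <- function(night_window = c(0L, 5L),
                      min_month_hours = 365,
                      corr_threshold = 0.7,
                      corr_mode = c("fixed", "mu3sigma"),
                      exclude_self = FALSE,
                      min_screen_pairs = 25,
                      gain = 0.49,
                      offset_reference = "ref_background",
                      min_offset_pairs = 24,
                      drift = list()) {
  corr_mode <- match.arg(corr_mode)
  drift_defaults <- list(
    min_run_days = 90, ssa_window = NULL, alpha = 0.05,
    fit_target = "raw", min_night_hours = 3
  )
  drift <- utils::modifyList(drift_defaults, drift)
  stopifnot(
    corr_threshold > 0, corr_threshold < 1,
    gain > 0, min_month_hours > 0, min_screen_pairs > 0,
    drift$alpha > 0, drift$alpha < 1, drift$min_run_days > 1
  )
  structure(
    list(
      night_window = as.integer(night_window),
      min_month_hours = min_month_hours,
      corr_threshold = corr_threshold,
      corr_mode = corr_mode,
      exclude_self = exclude_self,
      min_screen_pairs = min_screen_pairs,
      gain = gain,
      offset_reference = offset_reference,
      min_offset_pairs = min_offset_pairs,
      drift = drift
    ),
    class = "qa_config"
  )
}

n_lcs_rows <- function(data) sum(data$source == "lcs")

#' QA step 1: remove post-relocation records
#'
#' Every record of a registered sensor at or after its relocation
#' timestamp is removed; registry entries for unknown sensors are skipped
#' with a warning.
#'
#' @param data A network tibble.
#' @param registry Relocation registry tibble (`sensor_id`,
#'   `relocated_at`); defaults to the registry attached to `data`.
#' @return A list: `data` (filtered tibble) and `log` (one row per
#'   registry entry with the removed-record count).
#' @export
step1_relocation_filter <- function(data, registry = network_registry(data)) {
  if (is.null(registry) || nrow(registry) == 0) {
    return(list(data = data, log = tibble::tibble(
      sensor_id = character(), relocated_at = as.POSIXct(character(), tz = "UTC"),
      records_removed = integer()
    )))
  }
  unknown <- setdiff(registry$sensor_id, unique(data$sensor_id))
  if (length(unknown)) {
    warning(
      "registry entries for unknown sensor(s) skipped: ",
      paste(unknown, collapse = ", "),
      call. = FALSE
    )
    registry <- dplyr::filter(registry, !.data$sensor_id %in% unknown)
  }
  flagged <- data |>
    dplyr::left_join(registry, by = "sensor_id") |>
    dplyr::mutate(drop = !is.na(.data$relocated_at) &
      .data$timestamp >= .data$relocated_at)
  log <- flagged |>
    dplyr::filter(!is.na(.data$relocated_at)) |>
    dplyr::group_by(.data$sensor_id, .data$relocated_at) |>
    dplyr::summarise(records_removed = sum(.data$drop), .groups = "drop")
  list(
    data = flagged |> dplyr::filter(!.data$drop) |>
      dplyr::select(-"relocated_at", -"drop"),
    log = log
  )
}

hours_in_month <- function(month) {
  first <- as.Date(paste0(month, "-01"))
  nxt <- seq(first, by = "1 month", length.out = 2)[2]
  as.integer(nxt - first) * 24L
}

#' QA step 2: monthly coverage filter
#'
#' For each sensor and calendar month, counts the non-missing PM2.5 hours;
#' if the count is strictly below `min(min_month_hours, 0.5 * hours in the
#' month)` the whole sensor-month is removed. Reference stations are never
#' filtered.
#'
#' @param data A network tibble.
#' @param cfg A [qa_config()].
#' @return A list: `data` and `log` (per sensor-month: `valid_hours`,
#'   `threshold`, `disposition`).
#' @export
step2_coverage_filter <- function(data, cfg = qa_config()) {
  lcs <- dplyr::filter(data, .data$source == "lcs")
  cover <- lcs |>
    dplyr::mutate(month = month_of(.data$timestamp)) |>
    dplyr::group_by(.data$sensor_id, .data$month) |>
    dplyr::summarise(valid_hours = sum(!is.na(.data$pm25)), .groups = "drop") |>
    dplyr::mutate(
      threshold = pmin(cfg$min_month_hours, 0.5 * vapply(.data$month, hours_in_month, 1L)),
      disposition = ifelse(.data$valid_hours < .data$threshold,
        "dropped-coverage", "kept"
      )
    )
  dropped <- dplyr::filter(cover, .data$disposition == "dropped-coverage")
  out <- data |>
    dplyr::mutate(month = month_of(.data$timestamp)) |>
    dplyr::anti_join(
      dropped |> dplyr::select("sensor_id", "month"),
      by = c("sensor_id", "month")
    ) |>
    dplyr::select(-"month")
  list(data = out, log = cover)
}

#' QA step 3: blind network correlation screen
#'
#' For each calendar month, forms the hour-by-hour network mean over all
#' sensors present that hour and computes each sensor's Pearson r against
#' it on nighttime hours. A sensor-month whose r falls at or below the
#' threshold (fixed mode) or below the month's mean minus three standard
#' deviations of all r values (`mu3sigma` mode) is removed. Sensor-months
#' with too few paired night hours are kept but flagged; a constant
#' (zero-variance) sensor series fails the screen.
#'
#' @inheritParams step2_coverage_filter
#' @return A list: `data` and `log` (per sensor-month: `r`, `n_pairs`,
#'   `disposition`).
#' @export
step3_network_correlation_filter <- function(data, cfg = qa_config()) {
  lcs <- dplyr::filter(data, .data$source == "lcs") |>
    dplyr::mutate(month = month_of(.data$timestamp))
  if (length(unique(lcs$sensor_id)) < 2) {
    warning("single-sensor network: correlation screening skipped", call. = FALSE)
    return(list(data = data, log = tibble::tibble(
      sensor_id = character(), month = character(), r = numeric(),
      n_pairs = integer(), disposition = character()
    )))
  }
  night <- lcs |>
    dplyr::filter(is_night(.data$timestamp, cfg$night_window), !is.na(.data$pm25))
  net <- night |>
    dplyr::group_by(.data$month, .data$timestamp) |>
    dplyr::summarise(
      net_sum = sum(.data$pm25), net_n = dplyr::n(),
      .groups = "drop"
    )
  paired <- night |>
    dplyr::inner_join(net, by = c("month", "timestamp")) |>
    dplyr::mutate(net_mean = if (cfg$exclude_self) {
      ifelse(.data$net_n > 1, (.data$net_sum - .data$pm25) / (.data$net_n - 1), NA_real_)
    } else {
      .data$net_sum / .data$net_n
    }) |>
    dplyr::filter(!is.na(.data$net_mean))
  scr <- paired |>
    dplyr::group_by(.data$sensor_id, .data$month) |>
    dplyr::summarise(
      n_pairs = dplyr::n(),
      r = if (dplyr::n() >= 2 && stats::sd(.data$pm25) > 0 && stats::sd(.data$net_mean) > 0) {
        stats::cor(.data$pm25, .data$net_mean)
      } else {
        NA_real_
      },
      zero_var = dplyr::n() >= 2 && stats::sd(.data$pm25) == 0,
      .groups = "drop"
    )
  # months present in the data but with no night pairs at all
  all_months <- lcs |>
    dplyr::distinct(.data$sensor_id, .data$month) |>
    dplyr::anti_join(scr, by = c("sensor_id", "month")) |>
    dplyr::mutate(n_pairs = 0L, r = NA_real_, zero_var = FALSE)
  scr <- dplyr::bind_rows(scr, all_months)
  scr <- scr |>
    dplyr::group_by(.data$month) |>
    dplyr::mutate(
      cutoff = if (cfg$corr_mode == "fixed") {
        cfg$corr_threshold
      } else {
        mean(.data$r, na.rm = TRUE) - 3 * stats::sd(.data$r, na.rm = TRUE)
      }
    ) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      fails = .data$zero_var |
        (!is.na(.data$r) & (if (cfg$corr_mode == "fixed") {
          .data$r <= .data$cutoff
        } else {
          .data$r < .data$cutoff
        })),
      disposition = dplyr::case_when(
        .data$n_pairs < cfg$min_screen_pairs ~ "insufficient-for-screening",
        .data$fails ~ "dropped-correlation",
        TRUE ~ "kept"
      )
    ) |>
    dplyr::select("sensor_id", "month", "r", "n_pairs", "disposition")
  dropped <- dplyr::filter(scr, .data$disposition == "dropped-correlation")
  out <- data |>
    dplyr::mutate(month = month_of(.data$timestamp)) |>
    dplyr::anti_join(
      dropped |> dplyr::select("sensor_id", "month"),
      by = c("sensor_id", "month")
    ) |>
    dplyr::select(-"month")
  list(data = out, log = scr)
}

#' QA step 4: gain and weekly-offset correction
#'
#' Multiplies every sensor PM2.5 value by the gain correction factor, then
#' aligns each sensor's weekly mean with the background reference station:
#' for each sensor and ISO week the offset `mean(reference) -
#' mean(gain-corrected sensor)` over paired hours is added to that week.
#' Weeks with fewer than `min_offset_pairs` paired hours are left
#' uncorrected and flagged.
#'
#' @inheritParams step2_coverage_filter
#' @param reference Optional reference series tibble (`timestamp`, `pm25`);
#'   defaults to the `offset_reference` station inside `data`.
#' @return A list: `data` (corrected tibble) and `log` (per sensor-week:
#'   `offset`, `n_pairs`, `applied`).
#' @export
step4_gain_offset_correction <- function(data, cfg = qa_config(), reference = NULL) {
  if (is.null(reference)) {
    reference <- data |>
      dplyr::filter(.data$sensor_id == cfg$offset_reference) |>
      dplyr::select("timestamp", ref_pm25 = "pm25")
  } else {
    reference <- dplyr::select(reference, "timestamp", ref_pm25 = "pm25")
  }
  if (nrow(reference) == 0 || all(is.na(reference$ref_pm25))) {
    stop("offset reference series is entirely missing for the period", call. = FALSE)
  }
  corrected <- data |>
    dplyr::mutate(
      pm25 = ifelse(.data$source == "lcs", .data$pm25 * cfg$gain, .data$pm25),
      week = iso_week_of(.data$timestamp)
    )
  offsets <- corrected |>
    dplyr::filter(.data$source == "lcs") |>
    dplyr::left_join(reference, by = "timestamp") |>
    dplyr::filter(!is.na(.data$pm25), !is.na(.data$ref_pm25)) |>
    dplyr::group_by(.data$sensor_id, .data$week) |>
    dplyr::summarise(
      n_pairs = dplyr::n(),
      offset = mean(.data$ref_pm25) - mean(.data$pm25),
      .groups = "drop"
    ) |>
    dplyr::mutate(applied = .data$n_pairs >= cfg$min_offset_pairs)
  out <- corrected |>
    dplyr::left_join(
      offsets |> dplyr::filter(.data$applied) |>
        dplyr::select("sensor_id", "week", "offset"),
      by = c("sensor_id", "week")
    ) |>
    dplyr::mutate(
      pm25 = ifelse(.data$source == "lcs" & !is.na(.data$offset),
        .data$pm25 + .data$offset, .data$pm25
      )
    ) |>
    dplyr::select(-"week", -"offset")
  list(data = out, log = offsets)
}

#' QA step 5: SSA-based drift assessment
#'
#' For each sensor, builds the nightly bias series (sensor minus reference,
#' mean over paired nighttime hours per day) and finds the longest run of
#' consecutive valid days. Sensors with a run shorter than `min_run_days`
#' are `unassessed`. Otherwise the run is decomposed by [ssa_decompose()],
#' an ordinary least-squares line is fitted to the configured target (raw
#' nightly bias by default) against the day index, and the slope's
#' two-sided t-test decides the verdict: p-value at or below `alpha` means
#' `drifted`, above means `nondrifted`. Verdicts are annotations only; no
#' data is removed.
#'
#' @inheritParams step4_gain_offset_correction
#' @return A tibble, one row per sensor: `verdict`, `slope` (ug/m3 per
#'   day), `p_value`, `run_days`, `reason`.
#' @export
step5_drift_assessment <- function(data, cfg = qa_config(), reference = NULL) {
  if (is.null(reference)) {
    reference <- data |>
      dplyr::filter(.data$sensor_id == cfg$offset_reference) |>
      dplyr::select("timestamp", ref_pm25 = "pm25")
  } else {
    reference <- dplyr::select(reference, "timestamp", ref_pm25 = "pm25")
  }
  night_ref <- reference |>
    dplyr::filter(is_night(.data$timestamp, cfg$night_window))
  ref_cover <- mean(!is.na(night_ref$ref_pm25))
  lcs <- dplyr::filter(data, .data$source == "lcs")
  sensors <- unique(lcs$sensor_id)
  if (is.na(ref_cover) || ref_cover < 0.5) {
    return(tibble::tibble(
      sensor_id = sensors, verdict = "unassessed", slope = NA_real_,
      p_value = NA_real_, run_days = 0L,
      reason = "reference missing on > 50% of nights"
    ))
  }
  nightly <- lcs |>
    dplyr::filter(is_night(.data$timestamp, cfg$night_window)) |>
    dplyr::inner_join(night_ref, by = "timestamp") |>
    dplyr::filter(!is.na(.data$pm25), !is.na(.data$ref_pm25)) |>
    dplyr::mutate(day = day_of(.data$timestamp)) |>
    dplyr::group_by(.data$sensor_id, .data$day) |>
    dplyr::summarise(
      n_hours = dplyr::n(),
      bias = mean(.data$pm25 - .data$ref_pm25),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n_hours >= cfg$drift$min_night_hours)
  purrr::map_dfr(sensors, function(id) {
    b <- dplyr::filter(nightly, .data$sensor_id == id) |> dplyr::arrange(.data$day)
    if (nrow(b) == 0) {
      return(tibble::tibble(
        sensor_id = id, verdict = "unassessed", slope = NA_real_,
        p_value = NA_real_, run_days = 0L, reason = "no valid nightly bias"
      ))
    }
    # longest run of consecutive calendar days
    gap <- c(0, diff(as.integer(b$day)) != 1)
    run_id <- cumsum(gap)
    runs <- split(seq_len(nrow(b)), run_id)
    best <- runs[[which.max(lengths(runs))]]
    run <- b[best, ]
    if (nrow(run) < cfg$drift$min_run_days) {
      return(tibble::tibble(
        sensor_id = id, verdict = "unassessed", slope = NA_real_,
        p_value = NA_real_, run_days = nrow(run),
        reason = sprintf("longest run %d days < %d", nrow(run), cfg$drift$min_run_days)
      ))
    }
    dec <- ssa_decompose(run$bias, L = cfg$drift$ssa_window)
    target <- if (cfg$drift$fit_target == "ssa-trend") dec$trend else run$bias
    day_index <- as.integer(run$day - run$day[1])
    fit <- stats::lm(target ~ day_index)
    coefs <- summary(fit)$coefficients
    slope <- coefs["day_index", "Estimate"]
    p <- coefs["day_index", "Pr(>|t|)"]
    # a numerically perfect fit (zero residual variance) has no evidence of
    # drift unless the slope itself is non-negligible
    if (!is.finite(p)) p <- if (abs(slope) > 1e-8) 0 else 1
    tibble::tibble(
      sensor_id = id,
      verdict = ifelse(p <= cfg$drift$alpha, "drifted", "nondrifted"),
      slope = slope, p_value = p, run_days = nrow(run), reason = NA_character_
    )
  })
}

#' Run the full five-step quality assurance scheme
#'
#' Applies, in order: (1) relocation filter, (2) monthly coverage filter,
#' (3) blind network correlation screen, (4) gain and weekly-offset
#' correction, (5) SSA drift assessment (annotation only — no data is
#' removed in step 5). Reference-station records pass through untouched.
#'
#' @param data A network tibble (see [read_network()]).
#' @param cfg A [qa_config()].
#' @param registry Relocation registry; defaults to the one attached to
#'   `data`.
#' @return An object of class `aq_qa`: a list with `data` (the corrected
#'   network tibble), `report` (lists of per-step logs: `relocation`,
#'   `coverage`, `screening`, `offsets`, `drift`, and a `counts` tibble of
#'   sensor-record counts per step) and `cfg`.
#' @examples
#' sim <- simulate_network(
#'   synth_config(n_sensors = 6, n_hotspot_sensors = 2, n_days = 62),
#'   seed = 1
#' )
#' qa <- run_qa(sim$network)
#' glance(qa)
#' @export
run_qa <- function(data, cfg = qa_config(), registry = network_registry(data)) {
  n0 <- n_lcs_rows(data)
  s1 <- step1_relocation_filter(data, registry)
  n1 <- n_lcs_rows(s1$data)
  s2 <- step2_coverage_filter(s1$data, cfg)
  n2 <- n_lcs_rows(s2$data)
  s3 <- step3_network_correlation_filter(s2$data, cfg)
  n3 <- n_lcs_rows(s3$data)
  s4 <- step4_gain_offset_correction(s3$data, cfg)
  n4 <- n_lcs_rows(s4$data)
  drift <- step5_drift_assessment(s4$data, cfg)
  counts <- tibble::tibble(
    step = c(
      "input", "1 relocation", "2 coverage", "3 correlation",
      "4 gain/offset", "5 drift"
    ),
    records = c(n0, n1, n2, n3, n4, n4),
    removed = c(0L, n0 - n1, n1 - n2, n2 - n3, 0L, 0L)
  )
  structure(
    list(
      data = s4$data,
      report = list(
        relocation = s1$log, coverage = s2$log, screening = s3$log,
        offsets = s4$log, drift = drift, counts = counts
      ),
      cfg = cfg
    ),
    class = "aq_qa"
  )
}

#' @export
print.aq_qa <- function(x, ...) {
  cat("<aq_qa> five-step network quality assurance\n")
  print(x$report$counts)
  nd <- table(x$report$drift$verdict)
  cat("drift verdicts:", paste(names(nd), nd, sep = " = ", collapse = ", "), "\n")
  invisible(x)
}

#' Tidy the QA dispositions
#' @param x An `aq_qa` object from [run_qa()].
#' @param ... Unused.
#' @return A tibble of per-sensor-month dispositions from the coverage and
#'   correlation steps.
#' @export
tidy.aq_qa <- function(x, ...) {
  dplyr::full_join(
    x$report$coverage |>
      dplyr::select("sensor_id", "month", coverage_disposition = "disposition"),
    x$report$screening |>
      dplyr::select("sensor_id", "month", "r", screening_disposition = "disposition"),
    by = c("sensor_id", "month")
  )
}

#' Summarise a QA run
#' @param x An `aq_qa` object.
#' @param ... Unused.
#' @return One-row tibble: records in/out, removed per step, drift counts.
#' @export
glance.aq_qa <- function(x, ...) {
  ct <- x$report$counts
  tibble::tibble(
    records_in = ct$records[1],
    records_out = ct$records[nrow(ct)],
    removed_relocation = ct$removed[ct$step == "1 relocation"],
    removed_coverage = ct$removed[ct$step == "2 coverage"],
    removed_correlation = ct$removed[ct$step == "3 correlation"],
    n_drifted = sum(x$report$drift$verdict == "drifted"),
    n_nondrifted = sum(x$report$drift$verdict == "nondrifted"),
    n_unassessed = sum(x$report$drift$verdict == "unassessed")
  )
}
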