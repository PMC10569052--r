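test_that("relocation filter removes exactly the post-move records", {
  net <- tiny_network(72)
  # empty registry leaves everything untouched
  s <- step1_relocation_filter(net, registry = NULL)
  expect_equal(nrow(s$data), nrow(net))

  move_at <- as.POSIXct("2021-01-02 00:00:00", tz = "UTC")
  reg <- tibble::tibble(sensor_id = "s1", relocated_at = move_at)
  s <- step1_relocation_filter(net, reg)
  kept_s1 <- dplyr::filter(s$data, sensor_id == "s1")
  expect_true(all(kept_s1$timestamp < move_at))
  expect_equal(nrow(dplyr::filter(s$data, sensor_id == "s2")), 72)
  # removed count equals a brute-force count of post-move timestamps
  expect_equal(
    s$log$records_removed,
    sum(net$sensor_id == "s1" & net$timestamp >= move_at)
  )

  expect_warning(step1_relocation_filter(
    net,
    tibble::tibble(sensor_id = "ghost", relocated_at = move_at)
  ), "ghost")
})

test_that("relocation removal on a generated double-relocation scenario reconciles", {
  cfg <- small_cfg(relocations = tibble::tibble(
    sensor_id = c("lcs_01", "lcs_02"), day = c(10, 20)
  ))
  sim <- simulate_network(cfg, seed = 13)
  reg <- network_registry(sim$network)
  s <- step1_relocation_filter(sim$network, reg)
  brute <- sum(
    sim$network$sensor_id %in% reg$sensor_id &
      sim$network$timestamp >= reg$relocated_at[match(
        sim$network$sensor_id, reg$sensor_id
      )],
    na.rm = TRUE
  )
  expect_equal(sum(s$log$records_removed), brute)
  expect_equal(nrow(sim$network) - nrow(s$data), brute)
})

test_that("coverage filter applies the strict less-than monthly threshold", {
  # January: 744 h; build one sensor with exactly 365 valid hours and one
  # with 300, both present the whole month
  ts <- hourly_ts(744, "2021-01-01")
  mk <- function(id, n_valid) {
    pm <- rep(NA_real_, 744)
    pm[seq_len(n_valid)] <- 7
    tibble::tibble(
      sensor_id = id, timestamp = ts, pm25 = pm, rh = 80, temp = 0,
      easting = 100, northing = 100, neighborhood = "Grim", source = "lcs"
    )
  }
  net <- as_network(dplyr::bind_rows(mk("at365", 365), mk("at300", 300)))
  s <- step2_coverage_filter(net)
  expect_equal(
    dplyr::filter(s$log, sensor_id == "at365")$disposition, "kept"
  )
  expect_equal(
    dplyr::filter(s$log, sensor_id == "at300")$disposition, "dropped-coverage"
  )
  expect_equal(sort(unique(s$data$sensor_id)), "at365")

  # full-coverage synthetic season loses nothing
  sim <- simulate_network(small_cfg(), seed = 14)
  s2 <- step2_coverage_filter(sim$network)
  expect_equal(nrow(s2$data), nrow(sim$network))
})

test_that("short months use half the month, not the absolute threshold", {
  # February 2021: 672 h, so the cutoff is 336 h, not 365
  ts <- hourly_ts(672, "2021-02-01")
  pm <- rep(NA_real_, 672)
  pm[seq_len(340)] <- 7
  net <- as_network(tibble::tibble(
    sensor_id = "s1", timestamp = ts, pm25 = pm, rh = 80, temp = 0,
    easting = 100, northing = 100, neighborhood = "Grim", source = "lcs"
  ))
  expect_equal(step2_coverage_filter(net)$log$disposition, "kept")
})

test_that("correlation screen keeps coherent sensors and matches a brute-force r", {
  sim <- simulate_network(small_cfg(), seed = 15)
  s <- step3_network_correlation_filter(sim$network)
  expect_true(all(s$log$disposition %in% c("kept", "insufficient-for-screening")))

  # brute-force oracle for one sensor-month
  log1 <- s$log[which.max(s$log$n_pairs), ]
  lcs <- dplyr::filter(sim$network, source == "lcs")
  night <- dplyr::filter(
    lcs,
    format(timestamp, "%Y-%m", tz = "UTC") == log1$month,
    as.integer(format(timestamp, "%H", tz = "UTC")) < 5,
    !is.na(pm25)
  )
  netmean <- tapply(night$pm25, as.character(night$timestamp), mean)
  sensor <- dplyr::filter(night, sensor_id == log1$sensor_id)
  r_brute <- cor(sensor$pm25, netmean[as.character(sensor$timestamp)])
  expect_equal(log1$r, unname(r_brute), tolerance = 1e-12)
})

test_that("a corrupted sensor is screened out while the rest survive", {
  cfg <- small_cfg(corrupt_sensors = "lcs_03", n_days = 31)
  sim <- simulate_network(cfg, seed = 16)
  s <- step3_network_correlation_filter(sim$network)
  bad <- dplyr::filter(s$log, sensor_id == "lcs_03")
  good <- dplyr::filter(s$log, sensor_id != "lcs_03")
  expect_true(all(bad$disposition == "dropped-correlation"))
  expect_true(all(good$disposition == "kept"))
  expect_false("lcs_03" %in% s$data$sensor_id)
})

test_that("screening edge cases: constant output fails, single sensor skips, sparse flags", {
  ts <- hourly_ts(31 * 24, "2021-01-01")
  flat <- tibble::tibble(
    sensor_id = "flat", timestamp = ts, pm25 = 5, rh = 80, temp = 0,
    easting = 100, northing = 100, neighborhood = "Grim", source = "lcs"
  )
  varying <- lapply(1:3, function(i) {
    tibble::tibble(
      sensor_id = paste0("v", i), timestamp = ts,
      pm25 = 6 + 2 * sin(seq_along(ts) / 5) + i / 10, rh = 80, temp = 0,
      easting = 200 * i, northing = 100, neighborhood = "Grim", source = "lcs"
    )
  })
  net <- as_network(dplyr::bind_rows(c(list(flat), varying)))
  s <- step3_network_correlation_filter(net)
  expect_equal(
    dplyr::filter(s$log, sensor_id == "flat")$disposition,
    "dropped-correlation"
  )

  single <- as_network(varying[[1]])
  expect_warning(s1 <- step3_network_correlation_filter(single), "single-sensor")
  expect_equal(nrow(s1$data), nrow(single))

  sparse <- dplyr::bind_rows(varying) |>
    dplyr::filter(
      as.integer(format(timestamp, "%H", tz = "UTC")) >= 4 |
        timestamp >= as.POSIXct("2021-01-21", tz = "UTC")
    ) |>
    dplyr::filter(timestamp < as.POSIXct("2021-01-21", tz = "UTC"))
  s2 <- step3_network_correlation_filter(as_network(sparse))
  expect_true(all(s2$log$disposition == "insufficient-for-screening"))
})

test_that("gain and weekly offset correction recovers an affine-distorted sensor", {
  ts <- hourly_ts(24 * 21, "2021-01-04") # three ISO weeks
  ref_pm <- 6 + 2 * sin(seq_along(ts) / 7)
  net <- as_network(dplyr::bind_rows(
    tibble::tibble(
      sensor_id = "s1", timestamp = ts, pm25 = 2 * ref_pm, rh = 80, temp = 0,
      easting = 100, northing = 100, neighborhood = "Grim", source = "lcs"
    ),
    tibble::tibble(
      sensor_id = "ref_background", timestamp = ts, pm25 = ref_pm, rh = 80,
      temp = 0, easting = 900, northing = 900, neighborhood = "Kvadraturen",
      source = "reference"
    )
  ))
  s <- step4_gain_offset_correction(net, qa_config(gain = 0.5))
  out <- dplyr::filter(s$data, sensor_id == "s1")
  expect_equal(out$pm25, ref_pm, tolerance = 1e-12)
  expect_true(all(abs(s$log$offset) < 1e-12))

  # pure offset case: gain 1, sensor = ref + 3
  net2 <- net |> dplyr::mutate(pm25 = ifelse(source == "lcs", ref_pm + 3, pm25))
  s2 <- step4_gain_offset_correction(as_network(net2), qa_config(gain = 1))
  expect_equal(dplyr::filter(s2$data, sensor_id == "s1")$pm25, ref_pm,
    tolerance = 1e-12
  )
  expect_equal(unique(round(s2$log$offset, 10)), -3)
})

test_that("offset correction is equivariant to constant reference shifts", {
  sim <- simulate_network(small_cfg(), seed = 17)
  base <- step4_gain_offset_correction(sim$network)
  shifted_net <- sim$network |>
    dplyr::mutate(pm25 = ifelse(sensor_id == "ref_background", pm25 + 2.5, pm25))
  shifted <- step4_gain_offset_correction(as_network(shifted_net))
  a <- dplyr::filter(base$data, source == "lcs") |> dplyr::arrange(sensor_id, timestamp)
  b <- dplyr::filter(shifted$data, source == "lcs") |> dplyr::arrange(sensor_id, timestamp)
  expect_equal(b$pm25[!is.na(b$pm25)], (a$pm25 + 2.5)[!is.na(a$pm25)],
    tolerance = 1e-9
  )
})

test_that("sparse weeks are left uncorrected and a dead reference is an error", {
  ts <- hourly_ts(24 * 14, "2021-01-04")
  ref_pm <- rep(6, length(ts))
  ref_pm[25:length(ts)] <- NA # only 24 paired hours in week 1, 0 in week 2
  net <- as_network(dplyr::bind_rows(
    tibble::tibble(
      sensor_id = "s1", timestamp = ts, pm25 = 10, rh = 80, temp = 0,
      easting = 100, northing = 100, neighborhood = "Grim", source = "lcs"
    ),
    tibble::tibble(
      sensor_id = "ref_background", timestamp = ts, pm25 = ref_pm, rh = 80,
      temp = 0, easting = 900, northing = 900, neighborhood = "Kvadraturen",
      source = "reference"
    )
  ))
  s <- step4_gain_offset_correction(net, qa_config(gain = 1))
  expect_equal(sum(s$log$applied), 1) # exactly the 24-pair week
  # the uncorrected week keeps the gain-only value
  out <- dplyr::filter(s$data, sensor_id == "s1")
  expect_true(any(out$pm25 == 10))

  dead <- net |> dplyr::mutate(pm25 = ifelse(source == "reference", NA_real_, pm25))
  expect_error(
    step4_gain_offset_correction(as_network(dead), qa_config(gain = 1)),
    "entirely missing"
  )
})

test_that("drift assessment requires 90 consecutive days and flags injected drift", {
  mk_drift_net <- function(n_days, slope, noise_sd, seed) {
    set.seed(seed)
    hours <- 0:4
    ts <- as.POSIXct("2021-01-01 00:00:00", tz = "UTC") +
      rep((0:(n_days - 1)) * 86400, each = 5) + rep(hours * 3600, n_days)
    eps <- rep(rnorm(n_days, 0, noise_sd), each = 5)
    day_idx <- rep(0:(n_days - 1), each = 5)
    as_network(dplyr::bind_rows(
      tibble::tibble(
        sensor_id = "s1", timestamp = ts, pm25 = 10 + slope * day_idx + eps,
        rh = 80, temp = 0, easting = 100, northing = 100,
        neighborhood = "Grim", source = "lcs"
      ),
      tibble::tibble(
        sensor_id = "ref_background", timestamp = ts, pm25 = 10, rh = 80,
        temp = 0, easting = 900, northing = 900, neighborhood = "Kvadraturen",
        source = "reference"
      )
    ))
  }
  # 89 days is one short of assessable
  d89 <- step5_drift_assessment(mk_drift_net(89, 0.05, 1, 1))
  expect_equal(d89$verdict[d89$sensor_id == "s1"], "unassessed")

  d120 <- step5_drift_assessment(mk_drift_net(120, 0.05, 1, 2))
  expect_equal(d120$verdict[d120$sensor_id == "s1"], "drifted")
  expect_equal(d120$slope[d120$sensor_id == "s1"], 0.05, tolerance = 0.03)

  # reference gone for most nights: unassessed with reason
  net <- mk_drift_net(120, 0, 1, 3)
  gone <- net |>
    dplyr::mutate(pm25 = ifelse(
      source == "reference" & timestamp < as.POSIXct("2021-04-01", tz = "UTC"),
      NA_real_, pm25
    ))
  d <- step5_drift_assessment(as_network(gone))
  expect_equal(d$verdict[d$sensor_id == "s1"], "unassessed")
  expect_match(d$reason[d$sensor_id == "s1"], "reference")
})

test_that("the orchestrated five-step run conserves records and annotates drift", {
  cfg <- small_cfg(n_days = 90, missingness = 0.03)
  sim <- simulate_network(cfg, seed = 18)
  qa <- run_qa(sim$network)
  ct <- qa$report$counts
  expect_equal(
    ct$records[ct$step == "input"],
    sum(qa$data$source == "lcs") + sum(ct$removed)
  )
  expect_true(all(diff(ct$records[1:4]) <= 0)) # steps 1-3 only remove
  expect_true(all(qa$report$drift$verdict %in% c("drifted", "nondrifted", "unassessed")))
  expect_equal(nrow(glance(qa)), 1)

  # idempotence of the filtering steps 1-3
  once <- step3_network_correlation_filter(
    step2_coverage_filter(step1_relocation_filter(sim$network)$data)$data
  )$data
  twice <- step3_network_correlation_filter(
    step2_coverage_filter(step1_relocation_filter(once)$data)$data
  )$data
  expect_equal(nrow(twice), nrow(once))
  expect_equal(twice$pm25, once$pm25)
})

test_that("an identity-configured network passes untouched and nondrifted", {
  cfg <- small_cfg(
    n_days = 90, gain_mean = 1, gain_sd = 0, weekly_offset_sd = 0,
    noise_sd = 0, missingness = 0, daily_sdlog = 1e-9, hourly_sdlog = 1e-9,
    ref_noise_sd = 0
  )
  sim <- simulate_network(cfg, seed = 19)
  qa <- suppressWarnings(run_qa(sim$network, qa_config(gain = 1)))
  expect_equal(sum(qa$report$counts$removed), 0)
  expect_true(all(qa$report$drift$verdict == "nondrifted"))
})
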