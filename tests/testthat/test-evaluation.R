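test_that("zero innovation makes LOOCV a no-op with zero improvements", {
  g <- aq_grid(matrix(runif(100, 6, 12), 10, 10))
  set.seed(61)
  obs <- random_obs(g, 5)
  bg <- optimal_interpolation(g, obs, oi_config())$sites$background_at_site
  obs$value <- bg
  cv <- loocv(g, obs, oi_config())
  expect_equal(cv$sites$analysis, cv$sites$background, tolerance = 1e-10)
  imp <- dplyr::filter(cv$improvements, group == "all")
  expect_true(all(abs(imp$improvement_pct) < 1e-6 | is.na(imp$improvement_pct)))
})

test_that("held-out analyses match single-exclusion dense-oracle runs exactly", {
  g <- aq_grid(matrix(c(
    10, 11, 9, 10, 12,
    10, 10, 9, 11, 12,
    9, 10, 10, 10, 11,
    8, 9, 10, 11, 11,
    8, 9, 10, 10, 12
  ), 5, 5, byrow = TRUE))
  obs <- tibble::tibble(
    site_id = c("a", "b", "c"),
    easting = c(60, 250, 440), northing = c(60, 260, 430),
    value = c(14, 9, 12), var = c(1, 4, 2), source = "lcs"
  )
  cfg <- oi_config(sigma_b = 1.5, correlation_length = 250)
  cv <- loocv(g, obs, cfg)
  for (i in 1:3) {
    oracle <- oi_dense_oracle(g, obs[-i, ], cfg)
    own <- oi_dense_oracle(g, obs[i, ], cfg) # only for H at site i
    xa <- oracle$analysis
    # evaluate the excluded-site operator on the oracle analysis
    col <- min(max(floor(obs$easting[i] / g$cell_size) + 1, 1), g$nx)
    row <- min(max(floor(obs$northing[i] / g$cell_size) + 1, 1), g$ny)
    expect_equal(cv$sites$analysis[i], xa[row, col], tolerance = 1e-10)
  }
})

test_that("a held-out duplicate of a near-exact site is reproduced", {
  g <- aq_grid(matrix(10, 10, 10))
  obs <- tibble::tibble(
    site_id = c("kept", "held", "far"),
    easting = c(450, 450, 950), northing = c(450, 450, 150),
    value = c(14, 14, 11), var = c(1e-10, 1e-10, 1),
    source = "lcs"
  )
  cv <- suppressWarnings(loocv(g, obs, oi_config())) # duplicate-merge warning expected
  expect_equal(cv$sites$analysis[cv$sites$site_id == "held"], 14, tolerance = 1e-6)
})

test_that("improvement signs flip when background and analysis trade places", {
  g <- aq_grid(matrix(runif(144, 5, 14), 12, 12))
  set.seed(62)
  obs <- random_obs(g, 6)
  cv <- loocv(g, obs, oi_config())
  imp <- dplyr::filter(cv$improvements, group == "all")
  swapped <- 100 * (abs(imp$analysis) - abs(imp$background)) / abs(imp$analysis)
  expect_equal(sign(swapped), -sign(imp$improvement_pct))
})

test_that("an unbiased background with noise-dominated observations shows no gain", {
  deltas <- c()
  for (seed in 1:5) {
    cfg <- small_cfg(model_bias = 0, model_error_sd = 1e-9)
    tb <- generate_truth(cfg, seed)
    set.seed(seed + 900)
    obs <- random_obs(tb$model_field, 10)
    ops_bg <- optimal_interpolation(tb$model_field, obs, oi_config())$sites$background_at_site
    obs$value <- ops_bg + rnorm(10, 0, 1)
    obs$var <- 200^2 # sigma_o >> sigma_b
    cv <- loocv(tb$model_field, obs, oi_config())
    g <- glance(cv)
    deltas <- c(deltas, abs(g$rmse_improvement_pct))
  }
  expect_lt(max(deltas), 5)
})

test_that("diurnal cycle aggregation equals a brute-force group mean and finds the peaks", {
  net <- tiny_network(96)
  cyc <- diurnal_cycle(net, "station")
  expect_true(all(cyc$mean_pm25[cyc$group == "s1"] == 6))
  expect_equal(sort(unique(cyc$hour)), 0:23)

  sim <- simulate_network(small_cfg(), seed = 63)
  cyc <- diurnal_cycle(sim$network, "neighborhood")
  brute <- sim$network |>
    dplyr::filter(!is.na(pm25)) |>
    dplyr::mutate(hour = as.integer(format(timestamp, "%H", tz = "UTC"))) |>
    dplyr::group_by(neighborhood, hour) |>
    dplyr::summarise(m = mean(pm25), .groups = "drop")
  joined <- dplyr::inner_join(cyc, brute, by = c(group = "neighborhood", "hour"))
  expect_equal(joined$mean_pm25, joined$m, tolerance = 1e-12)

  # bimodal truth: the two highest local peaks fall in the observed windows
  for (grp in unique(cyc$group)) {
    prof <- dplyr::filter(cyc, group == grp) |> dplyr::arrange(hour)
    peak1 <- prof$hour[which.max(prof$mean_pm25)]
    expect_true(peak1 %in% 8:11 || peak1 %in% 16:22)
  }
})

test_that("neighborhood daily bands respect the 75% coverage rule", {
  # one sensor with 17 of 24 hours on day one: that day is excluded
  ts <- hourly_ts(48)
  pm <- c(rep(5, 17), rep(NA, 7), rep(6, 24))
  net <- as_network(tibble::tibble(
    sensor_id = "s1", timestamp = ts, pm25 = pm, rh = 80, temp = 0,
    easting = 1, northing = 1, neighborhood = "G", source = "lcs"
  ))
  agg <- neighborhood_daily(net)
  expect_equal(nrow(agg), 1)
  expect_equal(agg$day, as.Date("2021-01-02"))
  # single-sensor neighborhood: zero-width band
  expect_equal(agg$q25, agg$q75)
  expect_equal(agg$mean_pm25, 6)
})

test_that("neighborhood daily aggregation matches a brute-force oracle on gappy data", {
  sim <- simulate_network(small_cfg(missingness = 0.15), seed = 64)
  agg <- neighborhood_daily(sim$network)
  brute_daily <- sim$network |>
    dplyr::filter(source == "lcs") |>
    dplyr::mutate(day = as.Date(timestamp, tz = "UTC")) |>
    dplyr::group_by(sensor_id, neighborhood, day) |>
    dplyr::summarise(
      ok = sum(!is.na(pm25)) / 24 > 0.75,
      m = mean(pm25, na.rm = TRUE), .groups = "drop"
    ) |>
    dplyr::filter(ok)
  brute <- brute_daily |>
    dplyr::group_by(neighborhood, day) |>
    dplyr::summarise(
      mean_pm25 = mean(m),
      q25 = unname(quantile(m, 0.25, type = 7)),
      q75 = unname(quantile(m, 0.75, type = 7)),
      .groups = "drop"
    )
  joined <- dplyr::inner_join(agg, brute,
    by = c("neighborhood", "day"),
    suffix = c("", "_b")
  )
  expect_equal(nrow(joined), nrow(agg))
  expect_equal(joined$mean_pm25, joined$mean_pm25_b, tolerance = 1e-12)
  expect_equal(joined$q25, joined$q25_b, tolerance = 1e-12)
  expect_equal(joined$q75, joined$q75_b, tolerance = 1e-12)
})

test_that("plot constructors return ggplot objects", {
  sim <- simulate_network(small_cfg(), seed = 65)
  expect_s3_class(autoplot(sim$truth$truth_field), "ggplot")
  expect_s3_class(plot_diurnal(diurnal_cycle(sim$network, "neighborhood")), "ggplot")
  expect_s3_class(plot_neighborhood_daily(neighborhood_daily(sim$network)), "ggplot")
  obs <- seasonal_observations(sim$network)
  oi <- optimal_interpolation(sim$truth$model_field, obs)
  expect_s3_class(autoplot(oi), "ggplot")
  cv <- loocv(sim$truth$model_field, obs)
  expect_s3_class(autoplot(cv), "ggplot")
  expect_s3_class(autoplot(ssa_decompose(rnorm(60))), "ggplot")
  d <- generate_colocation(seed = 1)
  expect_s3_class(autoplot(robust_fit(d, sensor, ref)), "ggplot")
})
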