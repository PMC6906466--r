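make_sentinel <- function(counts_by_hour, n_days = 10) {
  # counts_by_hour: detections per hour per day (length 24)
  rows <- list()
  for (d in seq_len(n_days)) {
    for (h in 0:23) {
      n <- counts_by_hour[h + 1]
      if (n == 0) next
      ts <- sprintf("2013-01-%02d %02d:%02d:00", d, h,
                    floor(seq(0, 59, length.out = n)))
      rows <- c(rows, lapply(ts, function(t) c("SENT1", "R01", t)))
    }
  }
  toy_detections(rows)
}

test_that("a uniform sentinel record gives a flat SDF profile", {
  sdf <- sentinel_sdf(make_sentinel(rep(4, 24)))
  expect_equal(sdf$sdf, rep(1, 24))
  expect_equal(mean(sdf$sdf), 1, tolerance = 1e-9)
})

test_that("a 2x night-biased sentinel gives the 4/3 vs 2/3 profile", {
  # twice as many detections 00:00-11:59 as 12:00-23:59
  sdf <- sentinel_sdf(make_sentinel(c(rep(8, 12), rep(4, 12))))
  expect_equal(sdf$sdf[sdf$hour < 12], rep(4 / 3, 12))
  expect_equal(sdf$sdf[sdf$hour >= 12], rep(2 / 3, 12))
})

test_that("zero sentinel hours error without a floor, and the floored
           profile still averages one", {
  counts <- rep(4, 24); counts[5] <- 0
  expect_error(sentinel_sdf(make_sentinel(counts), floor = 0), "floor")
  sdf <- sentinel_sdf(make_sentinel(counts), floor = 0.1)
  expect_equal(mean(sdf$sdf), 1, tolerance = 1e-9)
  expect_true(all(sdf$sdf > 0))
})

test_that("standardisation divides by the SDF and renormalises", {
  # uniform shark + uniform sdf -> all hours 1/24, squeezed into (0,1)
  shark <- make_sentinel(rep(3, 24), n_days = 2)
  shark$tag_id <- "S1"
  flat <- sentinel_sdf(make_sentinel(rep(4, 24)))
  std <- standardize_hourly_proportions(shark, flat)
  expect_equal(std$p_std, rep(1 / 24, 24))
  expect_true(all(std$p_beta > 0 & std$p_beta < 1))
  # uniform shark / biased sdf -> daytime hours up-weighted 2x
  biased <- sentinel_sdf(make_sentinel(c(rep(8, 12), rep(4, 12))))
  std2 <- standardize_hourly_proportions(shark, biased)
  day <- std2$p_std[std2$hour >= 12]
  night <- std2$p_std[std2$hour < 12]
  expect_equal(unique(round(day / night, 10)), 2)
  expect_equal(sum(std2$p_std), 1)
  # animals with too few detections are dropped with a warning
  sparse <- shark[1:5, ]
  sparse$tag_id <- "S2"
  expect_warning(
    out <- standardize_hourly_proportions(dplyr::bind_rows(shark, sparse),
                                          flat),
    "fewer than"
  )
  expect_false("S2" %in% out$shark_id)
})

test_that("centre of activity is the detection-weighted mean distance", {
  rec <- toy_receivers(c(0, 2, 4, 7.5, 8))
  mk <- function(recs) {
    toy_detections(lapply(seq_along(recs), function(i) {
      c("S1", recs[i], sprintf("2013-01-05 03:%02d:00", i))
    }))
  }
  expect_equal(coa_distance(mk(c("R02", "R02", "R02", "R03", "R03", "R03")),
                            rec), 3)
  expect_equal(coa_distance(mk(rep("R04", 5)), rec), 7.5)
  expect_equal(coa_distance(mk(c("R01", "R05", "R05", "R05")), rec), 6)
  expect_error(coa_distance(mk("R99"), rec), "unknown receiver")
})

test_that("hourly COA stays in the convex hull of detected receivers", {
  cfg <- sim_config(seed = 5, n_sharks = 3, n_days = 20,
                    study_start = "2013-01-10")
  sim <- simulate_harbour(cfg)
  coa <- hourly_coa(sim$detections, sim$receivers)
  dist_of <- sim$receivers$distance_to_entrance_km
  names(dist_of) <- sim$receivers$receiver_id
  hulls <- sim$detections |>
    dplyr::mutate(hour_bin = lubridate::floor_date(timestamp, "hour"),
                  d = dist_of[receiver_id]) |>
    dplyr::group_by(shark_id = tag_id, hour_bin) |>
    dplyr::summarise(lo = min(d), hi = max(d), .groups = "drop")
  j <- dplyr::left_join(coa, hulls, by = c("shark_id", "hour_bin"))
  expect_true(all(j$coa_distance_km >= j$lo - 1e-9 &
                    j$coa_distance_km <= j$hi + 1e-9))
})

test_that("tide joining is exact-hour with flagged gaps", {
  act <- tibble::tibble(
    shark_id = "S1",
    hour_bin = as.POSIXct("2013-01-05 00:00:00", tz = "UTC") +
      3600 * (0:5),
    hour = 0:5, coa_distance_km = 1, n_detections = 2L
  )
  tides <- tibble::tibble(
    timestamp = as.POSIXct("2013-01-05 00:00:00", tz = "UTC") +
      3600 * c(0:3, 5),
    tide_m = c(1, 1.2, 1.4, 1.2, 0.8)
  )
  out <- join_tide(act, tides)
  expect_equal(attr(out, "n_tide_missing"), 1L)
  expect_true(out$tide_missing[out$hour == 4])
  expect_equal(out$tide_m[out$hour == 5], 0.8)
  # a simulated semidiurnal series joins back to the generator's values
  cfg <- sim_config(seed = 2, n_sharks = 2, n_days = 10,
                    study_start = "2013-01-10")
  sim <- simulate_harbour(cfg)
  coa <- hourly_coa(sim$detections, sim$receivers)
  jt <- join_tide(coa, sim$tides)
  expect_equal(attr(jt, "n_tide_missing"), 0L)
  h_idx <- as.numeric(difftime(jt$hour_bin, sim$tides$timestamp[1],
                               units = "hours"))
  expect_equal(jt$tide_m,
               cfg$tide_mean_m + cfg$tide_amplitude_m *
                 sin(2 * pi * h_idx / cfg$tide_period_h),
               tolerance = 1e-12)
})

test_that("water-column position maps surface to 0 and seafloor to 1", {
  rec <- toy_receivers(c(1, 3), depth = 10)  # max_depth_m = 16
  dets <- toy_detections(list(
    c("S1", "R01", "2013-01-05 01:00:00", "16"),
    c("S1", "R01", "2013-01-05 02:00:00", "0"),
    c("S1", "R02", "2013-01-05 03:00:00", "8")
  ))
  wc <- water_column_position(dets, rec)
  expect_equal(wc$position, c(1, 0, 0.5))
  # readings deeper than the chart clamp to 1 with a warning
  deep <- toy_detections(list(c("S1", "R01", "2013-01-05 01:00:00", "20")))
  expect_warning(wcd <- water_column_position(deep, rec), "clamped")
  expect_equal(wcd$position, 1)
  expect_equal(attr(wcd, "n_clamped"), 1L)
  bad <- rec
  bad$max_depth_m <- 0
  expect_error(water_column_position(dets, bad), "positive")
  expect_error(water_column_position(dets, rec[, -6]), "max_depth_m")
})

test_that("hourly water-column position recovers the diel depth cycle", {
  cfg <- sim_config(seed = 9, n_sharks = 4, n_days = 40,
                    study_start = "2013-01-05", frac_pressure_tags = 1)
  sim <- simulate_harbour(cfg)
  wc <- suppressWarnings(water_column_position(sim$detections,
                                               sim$receivers))
  hourly <- wc |>
    dplyr::group_by(hour) |>
    dplyr::summarise(depth = mean(depth_m), .groups = "drop")
  # deepest hour within 2 h of the generating peak (13:00)
  peak <- hourly$hour[which.max(hourly$depth)]
  expect_lte(min(abs(peak - cfg$depth_peak_hour),
                 24 - abs(peak - cfg$depth_peak_hour)), 2)
  # recovered amplitude within 30% of the generating amplitude
  amp_hat <- (max(hourly$depth) - min(hourly$depth)) / 2
  expect_lt(abs(amp_hat - cfg$depth_amplitude_m),
            0.3 * cfg$depth_amplitude_m)
})
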