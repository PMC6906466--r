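cal_study <- study_calendar("2009-01-01", "2015-05-29")

test_that("the two-detection rule defines a presence day", {
  dets <- toy_detections(list(
    c("S1", "R01", "2013-01-05 04:00:00"),                # 1 det -> absent
    c("S1", "R01", "2013-01-06 04:00:00"),                # 2 dets -> present
    c("S1", "R02", "2013-01-06 23:59:59"),
    c("S2", "R01", "2013-01-06 10:00:00")                 # 1 det -> absent
  ))
  pd <- presence_days(dets)
  expect_equal(nrow(pd), 1)
  expect_equal(pd$shark_id, "S1")
  expect_equal(pd$date, as.Date("2013-01-06"))
  expect_equal(pd$n_receivers_visited, 2L)
  expect_error(presence_days(dets, min_per_day = 0), "min_per_day")
})

test_that("days split 2/719/719 across three days are all presence days", {
  rows <- c(
    sprintf("2013-01-01 00:%02d:00", 0:1),
    sprintf("2013-01-02 %02d:%02d:00", rep(0:23, each = 30), 0:29)[1:719],
    sprintf("2013-01-03 %02d:%02d:00", rep(0:23, each = 30), 0:29)[1:719]
  )
  dets <- toy_detections(lapply(rows, function(ts) c("S1", "R01", ts)))
  expect_equal(nrow(presence_days(dets)), 3)
})

test_that("residency index reproduces printed 2-dp values", {
  expect_equal(round(residency_index(380, 1954), 2), 0.19)
  expect_equal(round(residency_index(92, 862), 2), 0.11)
  expect_equal(residency_index(0, 1000), 0)
  expect_error(residency_index(5, 0), "positive")
  expect_error(residency_index(10, 5), "days_detected")
})

test_that("presence-derived outputs ignore within-day duplication", {
  cfg <- sim_config(seed = 4, n_sharks = 2, n_days = 25,
                    study_start = "2013-01-10")
  sim <- simulate_harbour(cfg)
  pd1 <- presence_days(sim$detections)
  dup <- dplyr::bind_rows(sim$detections, sim$detections)
  pd2 <- presence_days(dup)
  expect_equal(pd1[c("shark_id", "date", "n_receivers_visited")],
               pd2[c("shark_id", "date", "n_receivers_visited")])
})

test_that("arrival/departure are the first/last presence days per year", {
  dets <- toy_detections(list(
    c("S1", "R01", "2013-01-05 01:00:00"), c("S1", "R01", "2013-01-05 02:00:00"),
    c("S1", "R01", "2013-02-02 01:00:00"), c("S1", "R01", "2013-02-02 02:00:00")
  ))
  pd <- presence_days(dets)
  # tagged in the 2011 shark-year, so 2012 shark-year arrivals are real
  ad <- arrival_departure(pd, cal_study,
                          tag_dates = c(S1 = as.Date("2012-06-01")))
  expect_equal(nrow(ad), 1)
  expect_equal(ad$arrival_month, 1)
  expect_equal(ad$departure_month, 2)
  # tagging-year arrivals are unavailable but departures still reported
  ad2 <- arrival_departure(pd, cal_study,
                           tag_dates = c(S1 = as.Date("2013-01-05")))
  expect_false(ad2$arrival_available)
  expect_true(is.na(ad2$arrival_date))
  expect_equal(ad2$departure_date, as.Date("2013-02-02"))
  # a single presence day degenerates to arrival = departure
  ad3 <- arrival_departure(pd[1, ], cal_study)
  expect_equal(ad3$arrival_date, ad3$departure_date)
})

test_that("return years count post-tagging shark-years with presence", {
  pd <- tibble::tibble(shark_id = "S1",
                       date = as.Date(c("2013-02-01", "2014-01-15")),
                       n_detections = 2L, n_receivers_visited = 1L)
  ry <- return_years(pd, as.Date("2013-02-01"), cal_study)
  expect_equal(ry$years_returned, 1L)   # 2013 shark-year only
  expect_equal(ry$max_possible, 2L)     # Sep 2013, Sep 2014 boundaries
  ry0 <- return_years(pd[1, ], as.Date("2013-02-01"), cal_study)
  expect_equal(ry0$years_returned, 0L)
  ry_none <- return_years(pd[0, ], as.Date("2013-02-01"), cal_study)
  expect_equal(ry_none$years_returned, 0L)
})

test_that("monthly presence picks the smallest denominator", {
  sharks <- tibble::tibble(shark_id = "S1", tag_date = as.Date("2013-01-15"))
  dep <- toy_receivers(5, from = "2012-01-01", to = "2016-01-01")
  cal <- study_calendar("2013-01-01", "2013-03-31")
  # present 10 days in tagging month -> denominator 17 (days since tagged)
  pres <- tibble::tibble(
    shark_id = "S1",
    date = as.Date("2013-01-15") + c(0:9, 40:44),
    n_detections = 2L, n_receivers_visited = 1L
  )
  mp <- monthly_presence(pres, sharks, dep, cal)
  jan <- mp[mp$month == 1, ]
  expect_equal(jan$denominator, 17L)
  expect_equal(jan$denominator_rule, "days_since_tagged")
  expect_equal(jan$proportion, 10 / 17)
  # array deployed 20 days in a month -> days_deployed rule
  dep20 <- dep
  dep20$deploy_start <- as.Date("2013-03-01")
  dep20$deploy_end <- as.Date("2013-03-21")
  mp2 <- monthly_presence(pres, sharks, dep20,
                          study_calendar("2013-03-01", "2013-03-31"))
  mar <- mp2[mp2$month == 3, ]
  expect_equal(mar$denominator, 20L)
  expect_equal(mar$denominator_rule, "days_deployed")
  # full month fully present -> proportion 1
  pres_full <- tibble::tibble(
    shark_id = "S1", date = seq(as.Date("2013-03-01"),
                                as.Date("2013-03-31"), by = "day"),
    n_detections = 2L, n_receivers_visited = 1L
  )
  sharks_old <- tibble::tibble(shark_id = "S1",
                               tag_date = as.Date("2010-01-01"))
  mp3 <- monthly_presence(pres_full, sharks_old, dep,
                          study_calendar("2013-03-01", "2013-03-31"))
  expect_equal(mp3$proportion[mp3$month == 3], 1)
})

test_that("monthly presence days sum to days detected per shark-year", {
  cfg <- sim_config(seed = 6, n_sharks = 3, n_days = 200,
                    study_start = "2012-10-01")
  sim <- simulate_harbour(cfg)
  cal <- study_calendar(cfg$study_start, cfg$study_start + cfg$n_days - 1)
  pres <- presence_days(sim$detections)
  mp <- monthly_presence(pres, sim$sharks, sim$receivers, cal)
  by_year_mp <- mp |>
    dplyr::group_by(shark_id, shark_year) |>
    dplyr::summarise(days = sum(days_present), .groups = "drop")
  by_year_pd <- pres |>
    dplyr::mutate(shark_year = shark_year(date, cal)) |>
    dplyr::count(shark_id, shark_year, name = "days")
  joined <- dplyr::left_join(by_year_pd, by_year_mp,
                             by = c("shark_id", "shark_year"))
  expect_equal(joined$days.x, joined$days.y)
})

test_that("simulated residency tracks the generating occupancy", {
  # dense curtain guarantees >= 2 detections whenever a shark is present
  cfg <- sim_config(seed = 8, n_sharks = 6, n_days = 90,
                    study_start = "2012-12-15",
                    receiver_km = seq(0.5, 29.5, by = 1))
  sim <- simulate_harbour(cfg)
  cal <- study_calendar(cfg$study_start, cfg$study_start + cfg$n_days - 1)
  rs <- residency_summary(sim$detections, sim$sharks, sim$receivers, cal)
  p_true <- mean(sim$truth$presence$p_occupancy)
  n_days_tot <- sum(rs$days_monitored)
  se <- sqrt(p_true * (1 - p_true) / n_days_tot)
  expect_lt(abs(mean(rs$residency_index) - p_true), 4 * se + 0.02)
})
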