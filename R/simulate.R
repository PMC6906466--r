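#' Logistic detection-range curve
#'
#' Probability that a single transmission at along-channel distance `d`
#' from a receiver is logged: `p(d) = 1 / (1 + exp(k * (d - d50)))`, with
#' the half-detection distance `d50` set to the array's measured effective
#' detection range (250 m: the distance at which detection probability is
#' 50%) and steepness `k` calibrated so that `p(d50) = 0.5` exactly and
#' `p(0) > 0.99` at the default `k = 0.02` per metre.
#'
#' @param distance_m Distance(s) in metres.
#' @param half_distance_m Distance of 50% detectability (default 250).
#' @param steepness Logistic steepness per metre (default 0.02).
#' @return Detection probability in (0, 1).
#' @export
detection_probability <- function(distance_m, half_distance_m = 250,
                                  steepness = 0.02) {
  stats::plogis(-steepness * (distance_m - half_distance_m))
}

#' Simulator configuration
#'
#' Defaults encode the study conditions the pipeline is designed for: a
#' ~30 km linear estuary monitored by a curtain of receivers along the
#' thalweg; transmitters on a pseudo-random 30-90 s repeat; a logistic
#' detection-range curve with 50% detectability at 250 m; water
#' temperature following a seasonal sinusoid (mean 19 degC, amplitude
#' 5 degC, peaking 1 February so the trough falls in August); daily
#' occupancy that is logit-linear in temperature with probability 0.5 at
#' 22 degC; mean-reverting (OU) along-channel movement within the harbour;
#' and a diel depth sinusoid (mean 7.6 m, amplitude 2.5 m, deepest at
#' ~13:00, so animals ride deeper by day and shallower at night).
#'
#' `hotspot_centres_km` plants areas of increased use: on a fraction
#' `hotspot_attraction` of present days the animal's daily activity centre
#' is drawn near a planted centre (spread `hotspot_extent_km`, so elevated
#' use spans adjacent receivers); planted centres also get shallow, steep
#' habitat covariates, giving the hotspot-habitat model a known answer.
#' `diel_efficiency` multiplies detection probability by hour of day
#' (default flat 1) to inject a known diel detection-efficiency bias for
#' sentinel-standardisation checks.
#'
#' @param seed Integer seed; the same seed reproduces the simulation
#'   byte-for-byte.
#' @param n_sharks Number of tagged animals.
#' @param study_start First study day.
#' @param n_days Study length in days.
#' @param harbour_length_km Channel length (default 30).
#' @param receiver_km Receiver positions along the thalweg.
#' @param detection_half_distance_m,detection_steepness Detection curve.
#' @param transmit_interval_s Uniform transmission interval bounds
#'   (default c(30, 90)).
#' @param temp_mean_c,temp_amplitude_c,temp_peak_doy,temp_noise_sd
#'   Seasonal temperature sinusoid.
#' @param occupancy_intercept,occupancy_temp_coef,occupancy_temp_ref
#'   Daily occupancy: logit p = intercept + coef * (temp - ref).
#' @param movement_reversion,movement_sd_km Hourly OU reversion rate and
#'   innovation SD.
#' @param hotspot_centres_km,hotspot_attraction,hotspot_extent_km Hotspot
#'   planting (NULL disables).
#' @param depth_mean_m,depth_amplitude_m,depth_peak_hour,depth_sd_m Diel
#'   depth cycle for pressure tags.
#' @param frac_pressure_tags Fraction of animals with depth/temperature
#'   sensor tags (default 23/40).
#' @param sentinel_km Fixed sentinel transmitter positions (default 200 m
#'   upstream of the third receiver).
#' @param diel_efficiency Length-24 multiplier on detection probability by
#'   hour.
#' @param tide_mean_m,tide_amplitude_m,tide_period_h Semidiurnal tide.
#' @param rain_p_wet,rain_mean_mm Daily rainfall: wet-day probability and
#'   mean wet-day total.
#' @param store_transmissions Keep the full transmission record in the
#'   truth object (memory-heavy; for conservation checks on small runs).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1, n_sharks = 8, study_start = "2012-09-01",
                       n_days = 365, harbour_length_km = 30,
                       receiver_km = seq(1, 29, by = 2),
                       detection_half_distance_m = 250,
                       detection_steepness = 0.02,
                       transmit_interval_s = c(30, 90),
                       temp_mean_c = 19, temp_amplitude_c = 5,
                       temp_peak_doy = 32, temp_noise_sd = 0.6,
                       occupancy_intercept = 0, occupancy_temp_coef = 0.8,
                       occupancy_temp_ref = 22,
                       movement_reversion = 0.4, movement_sd_km = 0.8,
                       hotspot_centres_km = NULL, hotspot_attraction = 0.6,
                       hotspot_extent_km = 1,
                       depth_mean_m = 7.6, depth_amplitude_m = 2.5,
                       depth_peak_hour = 13, depth_sd_m = 1.5,
                       frac_pressure_tags = 23 / 40,
                       sentinel_km = NULL,
                       diel_efficiency = rep(1, 24),
                       tide_mean_m = 1, tide_amplitude_m = 0.8,
                       tide_period_h = 12.42,
                       rain_p_wet = 0.3, rain_mean_mm = 8,
                       store_transmissions = FALSE) {
  cfg <- as.list(environment())
  cfg$study_start <- as.Date(study_start)
  cfg$sentinel_km <- sentinel_km %||%
    (receiver_km[min(3L, length(receiver_km))] + 0.2)
  with(cfg, {
    stopifnot(
      n_sharks >= 1, n_days >= 1, harbour_length_km > 0,
      all(receiver_km >= 0 & receiver_km <= harbour_length_km),
      detection_half_distance_m > 0, detection_steepness > 0,
      length(transmit_interval_s) == 2,
      transmit_interval_s[1] > 0,
      transmit_interval_s[2] > transmit_interval_s[1],
      movement_reversion > 0, movement_sd_km > 0,
      length(diel_efficiency) == 24, all(diel_efficiency > 0),
      frac_pressure_tags >= 0, frac_pressure_tags <= 1,
      rain_p_wet >= 0, rain_p_wet <= 1
    )
  })
  if (!is.null(cfg$hotspot_centres_km)) {
    stopifnot(all(cfg$hotspot_centres_km >= 0 &
                    cfg$hotspot_centres_km <= cfg$harbour_length_km),
              cfg$hotspot_attraction >= 0, cfg$hotspot_attraction <= 1,
              cfg$hotspot_extent_km > 0)
  }
  structure(cfg, class = "sim_config")
}

sim_env_daily <- function(cfg, dates) {
  doy <- as.numeric(format(dates, "%j"))
  temp <- cfg$temp_mean_c + cfg$temp_amplitude_c *
    cos(2 * pi * (doy - cfg$temp_peak_doy) / 365.25) +
    rnorm(length(dates), 0, cfg$temp_noise_sd)
  t_idx <- as.numeric(dates - dates[1])
  moon <- (1 + cos(2 * pi * t_idx / 29.53)) / 2
  wet <- rbinom(length(dates), 1, cfg$rain_p_wet)
  rain <- wet * rgamma(length(dates), shape = 1, scale = cfg$rain_mean_mm)
  tibble::tibble(
    date = dates, water_temp_c = temp, rain_mm = rain,
    rain_prev_mm = c(NA_real_, utils::head(rain, -1)),
    moon_frac = moon
  )
}

sim_occupancy_prob <- function(cfg, temp) {
  stats::plogis(cfg$occupancy_intercept +
                  cfg$occupancy_temp_coef * (temp - cfg$occupancy_temp_ref))
}

# Transmission times (whole seconds within the day) for a set of days,
# pseudo-random uniform intervals. Returns list(day_index, second).
sim_transmission_times <- function(n_days_active, interval) {
  mean_int <- mean(interval)
  n_max <- ceiling(86400 / interval[1]) + 8L
  out_day <- integer(0); out_sec <- numeric(0)
  for (d in seq_len(n_days_active)) {
    gaps <- runif(n_max, interval[1], interval[2])
    tt <- cumsum(gaps)
    tt <- tt[tt < 86400]
    out_day <- c(out_day, rep(d, length(tt)))
    out_sec <- c(out_sec, floor(tt))
  }
  list(day = out_day, sec = out_sec)
}

# Bernoulli detection of transmissions at positions pos_km by each
# receiver, with the diel efficiency multiplier. Returns a logical matrix
# is unnecessary; returns data frame rows (tx index, receiver index).
sim_detect <- function(pos_km, hour, cfg) {
  rows_tx <- integer(0); rows_rec <- integer(0)
  eff <- cfg$diel_efficiency[hour + 1L]
  for (r in seq_along(cfg$receiver_km)) {
    d_m <- abs(pos_km - cfg$receiver_km[r]) * 1000
    near <- which(d_m < 1500)
    if (length(near) == 0L) next
    p <- detection_probability(d_m[near], cfg$detection_half_distance_m,
                               cfg$detection_steepness) * eff[near]
    hit <- near[runif(length(near)) < p]
    rows_tx <- c(rows_tx, hit)
    rows_rec <- c(rows_rec, rep(r, length(hit)))
  }
  list(tx = rows_tx, rec = rows_rec)
}

#' Simulate a monitored estuary
#'
#' Generates, from one seed, every input the analysis pipeline consumes:
#' a detection log, receiver deployment table (with habitat covariates and
#' charted maximum depths), shark metadata, sentinel-tag detections, the
#' daily environmental series, the hourly tide series, and a truth record
#' (per-shark presence days, the generating occupancy probabilities and
#' coefficients, and optionally the full transmission log).
#'
#' Animals enter the harbour by an independent daily Bernoulli draw whose
#' probability is logit-linear in water temperature; within the harbour
#' they follow a discretised mean-reverting walk along the 1-D channel
#' around a daily activity centre; pressure-tagged animals carry a diel
#' depth sinusoid; transmissions fire at uniform pseudo-random 30-90 s
#' intervals and are detected independently by each receiver with the
#' logistic range curve (times the configured diel efficiency).
#'
#' @param cfg A [sim_config()].
#' @return A list: `detections`, `receivers`, `sharks`, `sentinel`,
#'   `env_daily`, `tides`, `truth`.
#' @export
simulate_harbour <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  dates <- cfg$study_start + 0:(cfg$n_days - 1)
  env <- sim_env_daily(cfg, dates)

  # tides: mean estimated height each hour
  hours_abs <- seq(0, cfg$n_days * 24 - 1)
  tides <- tibble::tibble(
    timestamp = as.POSIXct(dates[1], tz = "UTC") + hours_abs * 3600,
    tide_m = cfg$tide_mean_m + cfg$tide_amplitude_m *
      sin(2 * pi * hours_abs / cfg$tide_period_h)
  )

  # receivers: continuous deployment, habitat covariates; planted hotspot
  # sites are shallow with steep drop-offs
  nr <- length(cfg$receiver_km)
  is_hot_site <- rep(FALSE, nr)
  if (!is.null(cfg$hotspot_centres_km)) {
    for (hc in cfg$hotspot_centres_km) {
      is_hot_site <- is_hot_site |
        abs(cfg$receiver_km - hc) <= cfg$hotspot_extent_km
    }
  }
  mean_depth <- ifelse(is_hot_site, runif(nr, 2, 5), runif(nr, 6, 15))
  max_slope <- ifelse(is_hot_site, runif(nr, 0.3, 0.5),
                      runif(nr, 0.05, 0.2))
  receivers <- tibble::tibble(
    receiver_id = sprintf("R%02d", seq_len(nr)),
    lat = -33.85 + 0.001 * seq_len(nr),
    lon = 151.28 - cfg$receiver_km / 93.2,
    distance_to_entrance_km = cfg$receiver_km,
    mean_depth_m = mean_depth,
    max_depth_m = mean_depth * 1.6,
    max_slope = max_slope,
    deploy_start = dates[1],
    deploy_end = dates[cfg$n_days] + 1L,
    planted_hotspot = is_hot_site
  )

  # sharks
  sharks <- tibble::tibble(
    shark_id = sprintf("S%02d", seq_len(cfg$n_sharks)),
    sex = ifelse(runif(cfg$n_sharks) < 0.7, "Male", "Female"),
    tl_cm = round(runif(cfg$n_sharks, 220, 322)),
    tag_date = dates[1],
    tag_type = ifelse(seq_len(cfg$n_sharks) <=
                        round(cfg$frac_pressure_tags * cfg$n_sharks),
                      "V16TP", "V16")
  )

  p_occ <- sim_occupancy_prob(cfg, env$water_temp_c)
  theta <- cfg$movement_reversion
  ou_a <- exp(-theta)
  ou_s <- cfg$movement_sd_km * sqrt((1 - exp(-2 * theta)) / (2 * theta))
  L <- cfg$harbour_length_km

  det_rows <- list()
  truth_presence <- list()
  truth_tx <- list()
  for (i in seq_len(cfg$n_sharks)) {
    present <- runif(cfg$n_days) < p_occ
    truth_presence[[i]] <- tibble::tibble(
      shark_id = sharks$shark_id[i], date = dates,
      present = present, p_occupancy = p_occ
    )
    pd <- which(present)
    if (length(pd) == 0L) next
    npd <- length(pd)
    # daily activity centre: planted hotspot or anywhere mid-channel
    use_hot <- if (!is.null(cfg$hotspot_centres_km)) {
      runif(npd) < cfg$hotspot_attraction
    } else rep(FALSE, npd)
    centre <- runif(npd, 0.05 * L, 0.95 * L)
    if (any(use_hot)) {
      hc <- cfg$hotspot_centres_km[
        sample.int(length(cfg$hotspot_centres_km), sum(use_hot),
                   replace = TRUE)]
      centre[use_hot] <- pmin(pmax(
        hc + rnorm(sum(use_hot), 0, cfg$hotspot_extent_km / 2), 0), L)
    }
    # hourly OU positions (25 knots per day, vectorised over days)
    xh <- matrix(0, npd, 25)
    xh[, 1] <- pmin(pmax(centre + rnorm(npd, 0, cfg$movement_sd_km), 0), L)
    for (h in 2:25) {
      xh[, h] <- centre + (xh[, h - 1] - centre) * ou_a +
        rnorm(npd, 0, ou_s)
      xh[, h] <- pmin(pmax(xh[, h], 0), L)
    }
    tx <- sim_transmission_times(npd, cfg$transmit_interval_s)
    hr <- floor(tx$sec / 3600)
    frac <- (tx$sec - hr * 3600) / 3600
    idx <- cbind(tx$day, hr + 1L)
    pos <- xh[idx] + frac * (xh[cbind(tx$day, hr + 2L)] - xh[idx])
    hit <- sim_detect(pos, hr, cfg)
    if (length(hit$tx) > 0L) {
      day_date <- dates[pd[tx$day[hit$tx]]]
      ts <- as.POSIXct(day_date, tz = "UTC") + tx$sec[hit$tx]
      depth <- if (sharks$tag_type[i] == "V16TP") {
        pmax(cfg$depth_mean_m + cfg$depth_amplitude_m *
               cos(2 * pi * (hr[hit$tx] - cfg$depth_peak_hour) / 24) +
               rnorm(length(hit$tx), 0, cfg$depth_sd_m), 0)
      } else rep(NA_real_, length(hit$tx))
      det_rows[[length(det_rows) + 1L]] <- tibble::tibble(
        tag_id = sharks$shark_id[i],
        receiver_id = receivers$receiver_id[hit$rec],
        timestamp = ts,
        depth_m = depth,
        temp_c = env$water_temp_c[match(day_date, dates)] +
          rnorm(length(hit$tx), 0, 0.2)
      )
    }
    if (cfg$store_transmissions) {
      truth_tx[[length(truth_tx) + 1L]] <- tibble::tibble(
        tag_id = sharks$shark_id[i],
        timestamp = as.POSIXct(dates[pd[tx$day]], tz = "UTC") + tx$sec,
        pos_km = pos
      )
    }
  }

  # sentinel tags: fixed position, transmitting every day
  sent_rows <- list()
  for (s in seq_along(cfg$sentinel_km)) {
    tx <- sim_transmission_times(cfg$n_days, cfg$transmit_interval_s)
    hr <- floor(tx$sec / 3600)
    pos <- rep(cfg$sentinel_km[s], length(tx$sec))
    hit <- sim_detect(pos, hr, cfg)
    if (length(hit$tx) > 0L) {
      sent_rows[[s]] <- tibble::tibble(
        tag_id = sprintf("SENT%d", s),
        receiver_id = receivers$receiver_id[hit$rec],
        timestamp = as.POSIXct(dates[tx$day[hit$tx]], tz = "UTC") +
          tx$sec[hit$tx],
        depth_m = NA_real_, temp_c = NA_real_
      )
    }
    if (cfg$store_transmissions) {
      truth_tx[[length(truth_tx) + 1L]] <- tibble::tibble(
        tag_id = sprintf("SENT%d", s),
        timestamp = as.POSIXct(dates[tx$day], tz = "UTC") + tx$sec,
        pos_km = pos
      )
    }
  }

  detections <- if (length(det_rows) > 0L) {
    dplyr::arrange(dplyr::bind_rows(det_rows), .data$timestamp,
                   .data$tag_id, .data$receiver_id)
  } else {
    tibble::tibble(tag_id = character(), receiver_id = character(),
                   timestamp = as.POSIXct(character(), tz = "UTC"),
                   depth_m = numeric(), temp_c = numeric())
  }
  list(
    detections = detections,
    receivers = receivers,
    sharks = sharks,
    sentinel = if (length(sent_rows) > 0L) dplyr::bind_rows(sent_rows)
               else detections[0, ],
    env_daily = env,
    tides = tides,
    truth = list(
      presence = dplyr::bind_rows(truth_presence),
      transmissions = if (cfg$store_transmissions) {
        dplyr::bind_rows(truth_tx)
      } else NULL,
      coefficients = list(
        occupancy_intercept = cfg$occupancy_intercept,
        occupancy_temp_coef = cfg$occupancy_temp_coef,
        occupancy_temp_ref = cfg$occupancy_temp_ref,
        depth_mean_m = cfg$depth_mean_m,
        depth_amplitude_m = cfg$depth_amplitude_m,
        depth_peak_hour = cfg$depth_peak_hour
      )
    )
  )
}

#' Simulate the daily presence/abundance table directly
#'
#' Runs only the environment + occupancy stages of the generator, emitting
#' the daily table that [run_hurdle_analysis()] consumes (as if every
#' present animal had been detected). This is the appropriate scale for
#' selection/recovery studies of the environmental models, where the
#' transmission-level machinery adds nothing but cost.
#'
#' @param cfg A [sim_config()].
#' @return A daily tibble with the same columns as [build_daily_table()],
#'   plus attribute `p_occupancy` (the generating daily probabilities).
#' @export
simulate_daily_presence <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  dates <- cfg$study_start + 0:(cfg$n_days - 1)
  env <- sim_env_daily(cfg, dates)
  p_occ <- sim_occupancy_prob(cfg, env$water_temp_c)
  n_present <- rbinom(cfg$n_days, cfg$n_sharks, p_occ)
  out <- tibble::tibble(
    date = dates,
    n_sharks_present = n_present,
    present = as.integer(n_present > 0),
    n_receivers_deployed = length(cfg$receiver_km),
    n_tagged_to_date = cfg$n_sharks
  )
  out <- dplyr::bind_cols(out, env[, -1])
  out <- out[!is.na(out$rain_prev_mm), , drop = FALSE]
  attr(out, "p_occupancy") <- p_occ
  out
}

#' Write a simulation to the pipeline's CSV dialects
#'
#' @param sim Output of [simulate_harbour()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_sim_csvs <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_detections(sim$detections, file.path(dir, "detections.csv"))
  write_detections(sim$sentinel, file.path(dir, "sentinel.csv"))
  readr::write_csv(sim$receivers, file.path(dir, "receivers.csv"),
                   progress = FALSE)
  readr::write_csv(sim$sharks, file.path(dir, "sharks.csv"),
                   progress = FALSE)
  readr::write_csv(sim$env_daily, file.path(dir, "env_daily.csv"),
                   progress = FALSE)
  tides <- dplyr::mutate(sim$tides, timestamp = format(.data$timestamp,
    "%Y-%m-%d %H:%M:%S", tz = "UTC"))
  readr::write_csv(tides, file.path(dir, "tides_hourly.csv"),
                   progress = FALSE)
  invisible(dir)
}
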