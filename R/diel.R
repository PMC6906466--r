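#' Standardised detection frequency (SDF) profile from sentinel tags
#'
#' Moored sentinel transmitters measure the array's detection efficiency.
#' The SDF for hour `h` is the mean number of sentinel detections logged in
#' hour `h` per sentinel-day, normalised by the grand mean across the 24
#' hours, so the profile averages exactly 1. Dividing an animal's hourly
#' detection proportions by this profile removes diel detection-efficiency
#' bias (e.g. night-time noise reducing receiver performance).
#'
#' Sparse sentinel hours are floored at `floor` before renormalisation to
#' prevent division blow-ups downstream; with `floor = 0`, any hour with no
#' sentinel detections at all is an error.
#'
#' @param sentinel_dets Detection tibble for the sentinel tag(s).
#' @param floor Minimum raw SDF value (default 0.1). Set 0 to disable.
#' @return A 24-row tibble: `hour` (0-23), `sdf` (mean 1).
#' @export
sentinel_sdf <- function(sentinel_dets, floor = 0.1) {
  if (nrow(sentinel_dets) == 0L) {
    stop("no sentinel detections supplied", call. = FALSE)
  }
  hrs <- lubridate::hour(sentinel_dets$timestamp)
  days <- as.Date(sentinel_dets$timestamp, tz = "UTC")
  n_days <- dplyr::n_distinct(days)
  counts <- tabulate(hrs + 1L, nbins = 24L)
  if (any(counts == 0L) && floor <= 0) {
    stop("hour(s) ", paste(which(counts == 0L) - 1L, collapse = ", "),
         " have zero sentinel detections; rerun with a positive `floor` ",
         "to impose a minimum standardised detection frequency",
         call. = FALSE)
  }
  per_day <- counts / n_days
  sdf <- per_day / mean(per_day)
  sdf <- pmax(sdf, floor)
  sdf <- sdf / mean(sdf)
  tibble::tibble(hour = 0:23, sdf = sdf)
}

#' Sentinel-standardised hourly detection proportions
#'
#' For each animal, the proportion of its detections falling in each hour
#' of the day is divided by the sentinel SDF for that hour, renormalised to
#' sum to one (`p_std`), and squeezed into the open interval (0,1)
#' (`p_beta`) for beta-family modelling using the Smithson-Verkuilen
#' transform `(y*(n-1) + 0.5) / n`, with `n` the number of shark-hour
#' observations entering the model. The raw divided (un-renormalised)
#' values are kept as `p_std_raw`.
#'
#' Only full-deployment days should be supplied (so receiver effort is
#' constant across hour bins); filter upstream with the deployment table.
#'
#' @param dets Detection tibble (one or more animals).
#' @param profile SDF profile from [sentinel_sdf()].
#' @param min_detections Animals with fewer total detections are dropped
#'   with a warning (default 24).
#' @return A tibble: `shark_id`, `hour`, `n`, `p_raw`, `p_std_raw`,
#'   `p_std`, `p_beta`.
#' @export
standardize_hourly_proportions <- function(dets, profile,
                                           min_detections = 24) {
  stopifnot(all(c("hour", "sdf") %in% names(profile)))
  counts <- dets |>
    dplyr::mutate(hour = lubridate::hour(.data$timestamp)) |>
    dplyr::count(shark_id = .data$tag_id, .data$hour)
  totals <- counts |>
    dplyr::group_by(.data$shark_id) |>
    dplyr::summarise(total = sum(.data$n), .groups = "drop")
  drop <- totals$shark_id[totals$total < min_detections]
  if (length(drop) > 0L) {
    warning("dropping ", length(drop),
            " animal(s) with fewer than ", min_detections, " detections: ",
            paste(drop, collapse = ", "), call. = FALSE)
  }
  keep <- setdiff(totals$shark_id, drop)
  if (length(keep) == 0L) {
    return(tibble::tibble(shark_id = character(), hour = integer(),
                          n = integer(), p_raw = numeric(),
                          p_std_raw = numeric(), p_std = numeric(),
                          p_beta = numeric()))
  }
  grid <- tidyr::expand_grid(shark_id = keep, hour = 0:23)
  out <- grid |>
    dplyr::left_join(counts, by = c("shark_id", "hour")) |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L)) |>
    dplyr::left_join(profile, by = "hour") |>
    dplyr::group_by(.data$shark_id) |>
    dplyr::mutate(
      p_raw = .data$n / sum(.data$n),
      p_std_raw = .data$p_raw / .data$sdf,
      p_std = .data$p_std_raw / sum(.data$p_std_raw)
    ) |>
    dplyr::ungroup()
  n_obs <- nrow(out)
  out$p_beta <- (out$p_std * (n_obs - 1) + 0.5) / n_obs
  dplyr::select(out, "shark_id", "hour", "n", "p_raw", "p_std_raw",
                "p_std", "p_beta")
}

#' Centre-of-activity distance for one hour bin
#'
#' The detection-count-weighted mean of the along-thalweg distances to the
#' entrance of the receivers that logged the animal in the bin — a single
#' 1-D position summary per hour.
#'
#' @param dets Detections within one hour bin.
#' @param receivers Receiver tibble with `receiver_id` and
#'   `distance_to_entrance_km`.
#' @return Distance in km.
#' @export
coa_distance <- function(dets, receivers) {
  if (nrow(dets) == 0L) stop("no detections in bin", call. = FALSE)
  d <- receivers$distance_to_entrance_km[
    match(dets$receiver_id, receivers$receiver_id)]
  if (any(is.na(d))) {
    stop("unknown receiver_id: ",
         paste(unique(dets$receiver_id[is.na(d)]), collapse = ", "),
         call. = FALSE)
  }
  mean(d)
}

#' Hourly centre-of-activity series
#'
#' Computes [coa_distance()] for every (animal, hour bin) with at least one
#' detection. Hour bins are closed-open `[h:00, h+1:00)` on the fixed local
#' offset.
#'
#' @param dets Detection tibble.
#' @param receivers Receiver tibble (unique `receiver_id` and
#'   `distance_to_entrance_km`).
#' @return A tibble: `shark_id`, `hour_bin` (POSIXct), `hour`,
#'   `coa_distance_km`, `n_detections`, `mean_depth_m`.
#' @export
hourly_coa <- function(dets, receivers) {
  rec <- dplyr::distinct(receivers, .data$receiver_id,
                         .data$distance_to_entrance_km)
  d <- rec$distance_to_entrance_km[match(dets$receiver_id, rec$receiver_id)]
  if (any(is.na(d))) {
    stop("unknown receiver_id: ",
         paste(unique(dets$receiver_id[is.na(d)]), collapse = ", "),
         call. = FALSE)
  }
  dets |>
    dplyr::mutate(
      dist = d,
      hour_bin = lubridate::floor_date(.data$timestamp, "hour")
    ) |>
    dplyr::group_by(shark_id = .data$tag_id, .data$hour_bin) |>
    dplyr::summarise(
      coa_distance_km = mean(.data$dist),
      n_detections = dplyr::n(),
      mean_depth_m = mean(.data$depth_m, na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      hour = lubridate::hour(.data$hour_bin),
      mean_depth_m = ifelse(is.nan(.data$mean_depth_m), NA_real_,
                            .data$mean_depth_m)
    ) |>
    dplyr::relocate("hour", .after = "hour_bin")
}

#' Join hourly tide heights onto an activity series
#'
#' Exact-hour join of the tide series onto each hour bin. Bins without a
#' matching tide hour are flagged (`tide_missing`) and should be excluded
#' from tide models; the number flagged is reported as an attribute.
#'
#' @param activity Hourly activity tibble from [hourly_coa()].
#' @param tides Tide tibble from [read_tides()] (top-of-hour `timestamp`,
#'   `tide_m`).
#' @return `activity` with `tide_m` and `tide_missing` columns; attribute
#'   `n_tide_missing`.
#' @export
join_tide <- function(activity, tides) {
  td <- dplyr::distinct(tides, .data$timestamp, .keep_all = TRUE)
  out <- dplyr::left_join(
    activity,
    dplyr::select(td, hour_bin = "timestamp", "tide_m"),
    by = "hour_bin"
  )
  out$tide_missing <- is.na(out$tide_m)
  attr(out, "n_tide_missing") <- sum(out$tide_missing)
  out
}

#' Water-column position of sensor-tag detections
#'
#' Sensor depth divided by the maximum charted depth within the receiver's
#' effective detection range (~250 m): 1 means the animal was at the
#' seafloor, 0 at the surface. Sensor readings exceeding the charted
#' maximum (sensor/chart mismatch) are clamped to 1; the number clamped is
#' reported both as a warning and as attribute `n_clamped`.
#'
#' @param dets Detection tibble with non-missing `depth_m` (pressure-tag
#'   transmissions).
#' @param receivers Receiver tibble with `receiver_id` and `max_depth_m`.
#' @return A tibble: `shark_id`, `timestamp`, `hour`, `receiver_id`,
#'   `depth_m`, `max_depth_m`, `position`.
#' @export
water_column_position <- function(dets, receivers) {
  if (!"max_depth_m" %in% names(receivers)) {
    stop("receivers must carry a max_depth_m column ",
         "(maximum charted depth within the detection range)",
         call. = FALSE)
  }
  rec <- dplyr::distinct(receivers, .data$receiver_id, .data$max_depth_m)
  dets <- dets[!is.na(dets$depth_m), , drop = FALSE]
  md <- rec$max_depth_m[match(dets$receiver_id, rec$receiver_id)]
  if (any(is.na(md))) {
    stop("unknown receiver_id: ",
         paste(unique(dets$receiver_id[is.na(md)]), collapse = ", "),
         call. = FALSE)
  }
  if (any(md <= 0)) {
    stop("max_depth_m must be positive for all receivers", call. = FALSE)
  }
  pos <- dets$depth_m / md
  n_clamped <- sum(pos > 1)
  if (n_clamped > 0L) {
    warning(n_clamped, " detection(s) deeper than the charted maximum ",
            "depth; clamped to position 1", call. = FALSE)
  }
  out <- tibble::tibble(
    shark_id = dets$tag_id,
    timestamp = dets$timestamp,
    hour = lubridate::hour(dets$timestamp),
    receiver_id = dets$receiver_id,
    depth_m = dets$depth_m,
    max_depth_m = md,
    position = pmin(pos, 1)
  )
  attr(out, "n_clamped") <- n_clamped
  out
}
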