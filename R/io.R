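#' Detection-file dialects
#'
#' A dialect maps the columns of a detection CSV export onto the internal
#' detection fields and fixes the local UTC offset used to define calendar
#' days and hour bins. Timestamps are stored internally in local *standard*
#' time on that fixed offset; daylight-saving shifts are deliberately not
#' applied, so day binning is reproducible.
#'
#' `dialect_default()` reads the plain dialect written by
#' [write_detections()] and the simulator. `dialect_vr2w()` maps a VR2W
#' receiver export (timestamps logged in UTC, converted to the configured
#' local offset on read).
#'
#' @param tag_id,receiver_id,timestamp,depth_m,temp_c Column names in the
#'   file. Sensor columns may be `NA` if absent.
#' @param utc_offset_hours Fixed local UTC offset, in hours, used for
#'   calendar days. Default 10 (Australian Eastern Standard Time).
#' @param timestamps_utc Logical; if `TRUE` timestamps in the file are UTC
#'   and are shifted by `utc_offset_hours` on read.
#' @param delim Field delimiter.
#' @return A list of class `det_dialect`.
#' @export
det_dialect <- function(tag_id = "tag_id", receiver_id = "receiver_id",
                        timestamp = "timestamp", depth_m = "depth_m",
                        temp_c = "temp_c", utc_offset_hours = 10,
                        timestamps_utc = FALSE, delim = ",") {
  structure(
    list(tag_id = tag_id, receiver_id = receiver_id, timestamp = timestamp,
         depth_m = depth_m, temp_c = temp_c,
         utc_offset_hours = utc_offset_hours,
         timestamps_utc = isTRUE(timestamps_utc), delim = delim),
    class = "det_dialect"
  )
}

#' @rdname det_dialect
#' @export
dialect_default <- function(utc_offset_hours = 10) {
  det_dialect(utc_offset_hours = utc_offset_hours)
}

#' @rdname det_dialect
#' @export
dialect_vr2w <- function(utc_offset_hours = 10) {
  det_dialect(
    tag_id = "Transmitter", receiver_id = "Receiver",
    timestamp = "Date and Time (UTC)",
    depth_m = "Sensor Value", temp_c = NA_character_,
    utc_offset_hours = utc_offset_hours, timestamps_utc = TRUE
  )
}

parse_local_timestamp <- function(x, dialect) {
  # ISO-8601 with or without an explicit offset, or "YYYY-MM-DD HH:MM:SS"
  # interpreted on the dialect's fixed offset. Internally the local clock
  # time is represented as POSIXct in tz "UTC" (a fixed-offset clock).
  ts <- suppressWarnings(lubridate::ymd_hms(x, tz = "UTC", quiet = TRUE))
  has_offset <- grepl("[+-][0-9]{2}:?[0-9]{2}$|Z$", x)
  shift_h <- ifelse(has_offset | dialect$timestamps_utc,
                    dialect$utc_offset_hours, 0)
  ts + shift_h * 3600
}

#' Read a detection log
#'
#' Reads one transmitter-ping-per-row detection CSVs. Malformed timestamp
#' rows are dropped and counted (attribute `n_malformed`); the read fails if
#' more than `max_bad_frac` of rows are unparseable.
#'
#' @param path CSV file path.
#' @param dialect A [det_dialect()]; default [dialect_default()].
#' @param max_bad_frac Maximum tolerated fraction of unparseable rows
#'   (default 0.01).
#' @return A tibble with columns `tag_id`, `receiver_id`, `timestamp`
#'   (POSIXct, local fixed-offset clock), `depth_m`, `temp_c`, sorted
#'   chronologically, with attributes `n_malformed` and `sorted = TRUE`.
#' @export
read_detections <- function(path, dialect = dialect_default(),
                            max_bad_frac = 0.01) {
  stopifnot(inherits(dialect, "det_dialect"))
  raw <- readr::read_delim(path, delim = dialect$delim,
                           show_col_types = FALSE, progress = FALSE,
                           col_types = readr::cols(.default = "c"))
  need <- c(dialect$tag_id, dialect$receiver_id, dialect$timestamp)
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0L) {
    stop("detection file is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  ts <- parse_local_timestamp(raw[[dialect$timestamp]], dialect)
  bad <- is.na(ts)
  n_bad <- sum(bad)
  if (nrow(raw) > 0L && n_bad / nrow(raw) > max_bad_frac) {
    stop(sprintf("%d of %d detection rows have unparseable timestamps",
                 n_bad, nrow(raw)), call. = FALSE)
  }
  num_or_na <- function(col) {
    if (is.na(col) || !col %in% names(raw)) return(rep(NA_real_, nrow(raw)))
    suppressWarnings(as.numeric(raw[[col]]))
  }
  out <- tibble::tibble(
    tag_id = as.character(raw[[dialect$tag_id]]),
    receiver_id = as.character(raw[[dialect$receiver_id]]),
    timestamp = ts,
    depth_m = num_or_na(dialect$depth_m),
    temp_c = num_or_na(dialect$temp_c)
  )
  out <- out[!bad, , drop = FALSE]
  if (any(!is.na(out$depth_m) & out$depth_m < 0)) {
    stop("negative sensor depths in detection file", call. = FALSE)
  }
  out <- dplyr::arrange(out, .data$timestamp, .data$tag_id,
                        .data$receiver_id)
  attr(out, "n_malformed") <- n_bad
  attr(out, "sorted") <- TRUE
  out
}

#' Write a detection log
#'
#' Writes the plain dialect read back by [read_detections()] with
#' [dialect_default()]; timestamps are written as local fixed-offset clock
#' times `"YYYY-MM-DD HH:MM:SS"`.
#'
#' @param dets Detection tibble as returned by [read_detections()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_detections <- function(dets, path) {
  out <- dplyr::mutate(
    dets,
    timestamp = format(.data$timestamp, "%Y-%m-%d %H:%M:%S", tz = "UTC")
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read the receiver deployment table
#'
#' One row per deployment interval. Expected columns: `receiver_id`, `lat`,
#' `lon`, `distance_to_entrance_km` (along-thalweg), `mean_depth_m`,
#' `max_slope`, `deploy_start`, `deploy_end` (half-open date interval), and
#' optionally `max_depth_m` (maximum charted depth within the ~250 m
#' effective detection range, required for water-column position work).
#'
#' @param path CSV file path.
#' @return A tibble; per-receiver interval overlap is validated.
#' @export
read_receivers <- function(path) {
  rec <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("receiver_id", "lat", "lon", "distance_to_entrance_km",
            "mean_depth_m", "max_slope", "deploy_start", "deploy_end")
  missing_cols <- setdiff(need, names(rec))
  if (length(missing_cols) > 0L) {
    stop("receiver file is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  rec$receiver_id <- as.character(rec$receiver_id)
  rec$deploy_start <- as.Date(rec$deploy_start)
  rec$deploy_end <- as.Date(rec$deploy_end)
  if (any(rec$distance_to_entrance_km < 0)) {
    stop("distance_to_entrance_km must be non-negative", call. = FALSE)
  }
  validate_deployment_intervals(rec)
  tibble::as_tibble(rec)
}

validate_deployment_intervals <- function(rec) {
  if (any(rec$deploy_end <= rec$deploy_start)) {
    stop("deployment intervals must have deploy_start < deploy_end",
         call. = FALSE)
  }
  by_r <- split(rec, rec$receiver_id)
  for (r in by_r) {
    if (nrow(r) < 2L) next
    r <- r[order(r$deploy_start), ]
    if (any(utils::head(r$deploy_end, -1) > utils::tail(r$deploy_start, -1))) {
      stop("overlapping deployment intervals for receiver ",
           r$receiver_id[1], call. = FALSE)
    }
  }
  invisible(rec)
}

#' Read the tag/animal metadata table
#'
#' Expected columns: `shark_id`, `sex` (`Male`/`Female`), `tl_cm` (total
#' length at tagging), `tag_date`, `tag_type` (`V16` or `V16TP`).
#'
#' @param path CSV file path.
#' @return A tibble.
#' @export
read_sharks <- function(path) {
  sh <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("shark_id", "sex", "tl_cm", "tag_date", "tag_type")
  missing_cols <- setdiff(need, names(sh))
  if (length(missing_cols) > 0L) {
    stop("shark file is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  sh$shark_id <- as.character(sh$shark_id)
  sh$tag_date <- as.Date(sh$tag_date)
  if (!all(sh$sex %in% c("Male", "Female"))) {
    stop("sex must be 'Male' or 'Female'", call. = FALSE)
  }
  if (any(sh$tl_cm <= 0)) stop("tl_cm must be positive", call. = FALSE)
  tibble::as_tibble(sh)
}

#' Read the daily environmental series
#'
#' Expected columns: `date`, `water_temp_c` (mean across loggers),
#' `rain_mm`, `moon_frac` (illuminated fraction in \[0,1\]); `rain_prev_mm`
#' is filled from the previous row when absent.
#'
#' @param path CSV file path.
#' @return A tibble sorted by date.
#' @export
read_env_daily <- function(path) {
  env <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("date", "water_temp_c", "rain_mm", "moon_frac")
  missing_cols <- setdiff(need, names(env))
  if (length(missing_cols) > 0L) {
    stop("environment file is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  env$date <- as.Date(env$date)
  env <- env[order(env$date), ]
  if (!"rain_prev_mm" %in% names(env)) {
    env$rain_prev_mm <- c(NA_real_, utils::head(env$rain_mm, -1))
  }
  if (any(env$moon_frac < 0 | env$moon_frac > 1, na.rm = TRUE)) {
    stop("moon_frac must lie in [0, 1]", call. = FALSE)
  }
  if (any(env$rain_mm < 0, na.rm = TRUE)) {
    stop("rain_mm must be non-negative", call. = FALSE)
  }
  tibble::as_tibble(env)
}

#' Read the hourly tidal-height series
#'
#' Expected columns: `timestamp` (top-of-hour local clock) and `tide_m`
#' (mean estimated height for that hour).
#'
#' @param path CSV file path.
#' @param dialect A [det_dialect()] supplying the local offset convention.
#' @return A tibble with POSIXct `timestamp` and numeric `tide_m`.
#' @export
read_tides <- function(path, dialect = dialect_default()) {
  td <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(.default = "c"))
  need <- c("timestamp", "tide_m")
  missing_cols <- setdiff(need, names(td))
  if (length(missing_cols) > 0L) {
    stop("tide file is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  tibble::tibble(
    timestamp = parse_local_timestamp(td$timestamp, dialect),
    tide_m = as.numeric(td$tide_m)
  )
}

#' Per-shark records from a seven-year Sydney Harbour monitoring study
#'
#' Packaged summary records for the 40 sub-adult and adult bull sharks
#' acoustically monitored in Sydney Harbour between 2009 and 2015: tag date,
#' sex, total length at tagging (cm), number of days detected, number of
#' days monitored, the residency index as printed (2 decimal places), the
#' number of shark-years in which the animal subsequently returned, and the
#' maximum number of years it was monitored.
#'
#' Days detected counts raw detection days (so the four animals recorded
#' only on their release day carry a 1 even though the two-detection
#' presence rule governs all presence-day analysis).
#'
#' @return A 40-row tibble.
#' @export
bullshark_records <- function() {
  path <- system.file("extdata", "sydney_bullshark_records.csv",
                      package = "estuarytrack", mustWork = TRUE)
  rec <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  rec$shark_id <- as.character(rec$shark_id)
  rec$tag_date <- as.Date(rec$tag_date)
  tibble::as_tibble(rec)
}
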