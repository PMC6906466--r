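#' Presence days from raw detections
#'
#' An animal counts as present in the estuary on a calendar day
#' (00:00-23:59 on the fixed local offset) only if at least `min_per_day`
#' detections of its tag were logged that day; the default of 2 discards
#' spurious single detections.
#'
#' @param dets Detection tibble (see [read_detections()]).
#' @param min_per_day Minimum detections per day for a presence day
#'   (default 2; must be >= 1).
#' @return A tibble with one row per (shark, day): `shark_id`, `date`,
#'   `n_detections`, `n_receivers_visited`.
#' @export
presence_days <- function(dets, min_per_day = 2) {
  if (min_per_day < 1) stop("min_per_day must be >= 1", call. = FALSE)
  if (nrow(dets) == 0L) {
    return(tibble::tibble(shark_id = character(), date = as.Date(character()),
                          n_detections = integer(),
                          n_receivers_visited = integer()))
  }
  dets |>
    dplyr::mutate(date = as.Date(.data$timestamp, tz = "UTC")) |>
    dplyr::group_by(shark_id = .data$tag_id, .data$date) |>
    dplyr::summarise(
      n_detections = dplyr::n(),
      n_receivers_visited = dplyr::n_distinct(.data$receiver_id),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n_detections >= min_per_day) |>
    dplyr::arrange(.data$shark_id, .data$date)
}

#' Residency index
#'
#' Days detected divided by days monitored; 1 means the animal was detected
#' every monitored day. Returned unrounded — round to 2 decimals only for
#' presentation.
#'
#' @param days_detected,days_monitored Non-negative integers (vectorised);
#'   `days_monitored` must be positive and at least `days_detected`.
#' @return Numeric ratio in \[0, 1\].
#' @export
residency_index <- function(days_detected, days_monitored) {
  if (any(days_monitored <= 0)) {
    stop("days_monitored must be positive", call. = FALSE)
  }
  if (any(days_detected < 0 | days_detected > days_monitored)) {
    stop("days_detected must lie in [0, days_monitored]", call. = FALSE)
  }
  days_detected / days_monitored
}

#' Arrival and departure by shark-year
#'
#' The arrival is the first presence day of each shark-year and the
#' departure the last. Arrivals are flagged unavailable for the shark-year
#' in which the animal was tagged (the tagging itself, not a return, opens
#' that year's record).
#'
#' @param presence Presence-day tibble from [presence_days()].
#' @param cal A [study_calendar()].
#' @param tag_dates Optional named Date vector (names = shark ids) used to
#'   flag the tagging shark-year.
#' @return A tibble: `shark_id`, `shark_year`, `arrival_date`,
#'   `departure_date`, `arrival_month`, `departure_month`,
#'   `arrival_available`.
#' @export
arrival_departure <- function(presence, cal, tag_dates = NULL) {
  stopifnot(inherits(cal, "study_calendar"))
  out <- presence |>
    dplyr::mutate(shark_year = shark_year(.data$date, cal)) |>
    dplyr::group_by(.data$shark_id, .data$shark_year) |>
    dplyr::summarise(
      arrival_date = min(.data$date),
      departure_date = max(.data$date),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      arrival_month = lubridate::month(.data$arrival_date),
      departure_month = lubridate::month(.data$departure_date)
    )
  if (!is.null(tag_dates)) {
    tag_year <- shark_year(tag_dates, cal)
    names(tag_year) <- names(tag_dates)
    out$arrival_available <-
      out$shark_year != tag_year[out$shark_id] |
      is.na(tag_year[out$shark_id])
    out$arrival_date[!out$arrival_available] <- as.Date(NA)
    out$arrival_month[!out$arrival_available] <- NA_integer_
  } else {
    out$arrival_available <- TRUE
  }
  out
}

#' Return-year accounting
#'
#' A shark "returns" in a shark-year after its tagging year when it has at
#' least one presence day (i.e. at least two detections on one day) in that
#' year. The maximum possible number of return years counts every
#' shark-year boundary (anchor day) between the tag date and the study end.
#'
#' @param presence Presence-day tibble for one shark.
#' @param tag_date The shark's tag date.
#' @param cal A [study_calendar()].
#' @return A list with `years_returned` and `max_possible`.
#' @export
return_years <- function(presence, tag_date, cal) {
  stopifnot(inherits(cal, "study_calendar"))
  tag_date <- as.Date(tag_date)
  tag_year <- shark_year(tag_date, cal)
  end_year <- shark_year(cal$study_end, cal)
  max_possible <- max(0L, end_year - tag_year)
  if (nrow(presence) == 0L) {
    return(list(years_returned = 0L, max_possible = max_possible))
  }
  yrs <- unique(shark_year(presence$date, cal))
  list(
    years_returned = sum(yrs > tag_year),
    max_possible = max_possible
  )
}

#' Monthly presence proportions
#'
#' Number of presence days per (shark, shark-year, month) divided by the
#' smallest of three candidate denominators: (i) days in the month, (ii)
#' days since tagging within the month (tag day inclusive), (iii) days with
#' at least one receiver deployed in the month. Months with a zero
#' denominator (entirely before tagging, or with no deployment) are
#' omitted.
#'
#' @param presence Presence-day tibble from [presence_days()].
#' @param sharks Shark metadata tibble with `shark_id` and `tag_date`.
#' @param deployments Receiver deployment tibble.
#' @param cal A [study_calendar()].
#' @return A tibble: `shark_id`, `shark_year`, `year`, `month`,
#'   `days_present`, `denominator`, `denominator_rule`, `proportion`.
#' @export
monthly_presence <- function(presence, sharks, deployments, cal) {
  stopifnot(inherits(cal, "study_calendar"))
  months <- seq(lubridate::floor_date(cal$study_start, "month"),
                lubridate::floor_date(cal$study_end, "month"), by = "month")
  dep_days <- deployment_days(deployments, cal$study_start, cal$study_end)
  pres <- presence |>
    dplyr::mutate(month_start = lubridate::floor_date(.data$date, "month")) |>
    dplyr::count(.data$shark_id, .data$month_start, name = "days_present")

  rows <- list()
  for (i in seq_len(nrow(sharks))) {
    sid <- sharks$shark_id[i]
    tag <- as.Date(sharks$tag_date[i])
    for (m0 in as.list(months)) {
      m1 <- lubridate::ceiling_date(m0, "month") - 1L
      m_end <- min(m1, cal$study_end)
      if (m_end < tag) next
      n_in_month <- as.integer(lubridate::days_in_month(m0))
      n_since_tag <- as.integer(m_end - max(m0, tag) + 1L)
      n_deployed <- sum(dep_days >= m0 & dep_days <= m_end)
      cand <- c(days_in_month = n_in_month,
                days_since_tagged = n_since_tag,
                days_deployed = n_deployed)
      denom <- min(cand)
      if (denom <= 0L) next
      rule <- names(cand)[which.min(cand)]
      dp <- pres$days_present[pres$shark_id == sid & pres$month_start == m0]
      dp <- if (length(dp) == 0L) 0L else dp
      rows[[length(rows) + 1L]] <- tibble::tibble(
        shark_id = sid,
        shark_year = shark_year(m0, cal),
        year = lubridate::year(m0),
        month = lubridate::month(m0),
        days_present = dp,
        denominator = as.integer(denom),
        denominator_rule = rule,
        proportion = dp / denom
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Per-shark residency summary
#'
#' Builds the one-row-per-shark study summary (days detected, days
#' monitored, residency index, return years) from detections and metadata.
#' `days_detected_raw` counts every day with at least one detection;
#' `days_detected` applies the two-detection presence rule. The residency
#' index uses raw detection days, matching the convention of the study
#' summary table this mirrors.
#'
#' @param dets Detection tibble.
#' @param sharks Shark metadata tibble.
#' @param deployments Receiver deployment tibble.
#' @param cal A [study_calendar()].
#' @param min_per_day Presence-day threshold (default 2).
#' @return A tibble with one row per shark.
#' @export
residency_summary <- function(dets, sharks, deployments, cal,
                              min_per_day = 2) {
  pres <- presence_days(dets, min_per_day = min_per_day)
  raw <- presence_days(dets, min_per_day = 1)
  out <- vector("list", nrow(sharks))
  for (i in seq_len(nrow(sharks))) {
    sid <- sharks$shark_id[i]
    tag <- as.Date(sharks$tag_date[i])
    dm <- days_monitored(tag, deployments, cal)
    p_i <- pres[pres$shark_id == sid, , drop = FALSE]
    r_i <- raw[raw$shark_id == sid, , drop = FALSE]
    ry <- return_years(p_i, tag, cal)
    out[[i]] <- tibble::tibble(
      shark_id = sid,
      sex = sharks$sex[i],
      tl_cm = sharks$tl_cm[i],
      tag_date = tag,
      days_detected = nrow(p_i),
      days_detected_raw = nrow(r_i),
      days_monitored = dm,
      residency_index = nrow(r_i) / dm,
      years_returned = ry$years_returned,
      max_years_monitored = ry$max_possible
    )
  }
  dplyr::bind_rows(out)
}
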