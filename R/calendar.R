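#' Study calendar with an anchored biological year
#'
#' Seasonal occupancy of the estuary spans the austral summer and autumn, so
#' annual accounting uses a "shark-year" beginning on 1 September rather than
#' the calendar year: one occupancy season then falls entirely within a single
#' year label.
#'
#' @param study_start,study_end Dates (or anything `as.Date()` accepts)
#'   delimiting the monitoring period. `study_start` must precede
#'   `study_end`.
#' @param year_anchor_month Integer month (1-12) on whose first day each
#'   shark-year begins. Default 9 (September).
#' @return An object of class `study_calendar`.
#' @examples
#' cal <- study_calendar("2009-01-01", "2015-05-29")
#' shark_year(as.Date("2013-01-16"), cal) # 2012: mid shark-year 2012
#' @export
study_calendar <- function(study_start, study_end, year_anchor_month = 9) {
  study_start <- as.Date(study_start)
  study_end <- as.Date(study_end)
  if (is.na(study_start) || is.na(study_end)) {
    stop("study_start and study_end must be valid dates", call. = FALSE)
  }
  if (study_start >= study_end) {
    stop("study_start must be before study_end", call. = FALSE)
  }
  year_anchor_month <- as.integer(year_anchor_month)
  if (year_anchor_month < 1L || year_anchor_month > 12L) {
    stop("year_anchor_month must be in 1..12", call. = FALSE)
  }
  structure(
    list(study_start = study_start, study_end = study_end,
         year_anchor_month = year_anchor_month),
    class = "study_calendar"
  )
}

#' @export
print.study_calendar <- function(x, ...) {
  cat("<study_calendar> ", format(x$study_start), " to ", format(x$study_end),
      ", years anchored on month ", x$year_anchor_month, "\n", sep = "")
  invisible(x)
}

#' Shark-year label of a date
#'
#' The shark-year `Y` spans `[Y-<anchor>-01, (Y+1)-<anchor>-01)`. With the
#' default September anchor, 2010-08-31 belongs to shark-year 2009 and
#' 2010-09-01 opens shark-year 2010. With `year_anchor_month = 1` the
#' shark-year equals the calendar year.
#'
#' @param d A Date vector.
#' @param cal A [study_calendar()].
#' @return Integer vector of shark-year labels.
#' @export
shark_year <- function(d, cal) {
  stopifnot(inherits(cal, "study_calendar"))
  d <- as.Date(d)
  y <- lubridate::year(d)
  m <- lubridate::month(d)
  as.integer(ifelse(m >= cal$year_anchor_month, y, y - 1L))
}

#' First day of a shark-year
#' @param y Integer shark-year label(s).
#' @param cal A [study_calendar()].
#' @return Date vector of the anchor day opening each shark-year.
#' @export
shark_year_start <- function(y, cal) {
  stopifnot(inherits(cal, "study_calendar"))
  as.Date(sprintf("%d-%02d-01", as.integer(y), cal$year_anchor_month))
}

# Dates (within [from, to]) on which at least one receiver deployment
# interval overlaps the day. Intervals are half-open [deploy_start,
# deploy_end): a retrieval at 00:00 of day d does not cover day d.
deployment_days <- function(deployments, from, to) {
  from <- as.Date(from); to <- as.Date(to)
  if (from > to) return(as.Date(character()))
  days <- seq(from, to, by = "day")
  if (is.null(deployments) || nrow(deployments) == 0L) {
    return(as.Date(character()))
  }
  covered <- rep(FALSE, length(days))
  ds <- as.Date(deployments$deploy_start)
  de <- as.Date(deployments$deploy_end)
  for (i in seq_along(ds)) {
    covered <- covered | (days >= ds[i] & days < de[i])
  }
  days[covered]
}

#' Days an animal was monitored
#'
#' Counts the calendar days strictly after the tag date, up to and including
#' the study end, on which at least one receiver was deployed. Monitoring is
#' taken to begin the day after tagging: the partial release day is not a
#' full monitored day, and with a continuously deployed array the count
#' equals the plain date difference `study_end - tag_date` (e.g. a shark
#' tagged 2013-01-17 and monitored to 2015-05-29 gives 862 days).
#'
#' @param tag_date Date the animal was tagged (must not be after the study
#'   end).
#' @param deployments Receiver deployment table with `deploy_start` /
#'   `deploy_end` columns (one row per deployment interval, half-open).
#' @param cal A [study_calendar()].
#' @return Integer number of monitored days.
#' @export
days_monitored <- function(tag_date, deployments, cal) {
  stopifnot(inherits(cal, "study_calendar"))
  tag_date <- as.Date(tag_date)
  if (is.na(tag_date)) stop("tag_date must be a valid date", call. = FALSE)
  if (tag_date > cal$study_end) {
    stop("tag_date is after the study end", call. = FALSE)
  }
  length(deployment_days(deployments, tag_date + 1L, cal$study_end))
}
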