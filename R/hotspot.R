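#' Receiver-level usage rates
#'
#' Total detections at each receiver divided by the number of days the
#' receiver was deployed ("detections per day deployed"), optionally
#' restricted to a period. Receivers deployed but never detecting get rate
#' 0; receivers with zero deployed days in the period are omitted.
#'
#' @param dets Detection tibble.
#' @param receivers Receiver deployment tibble (one row per interval).
#' @param period Optional length-2 date vector `c(from, to)` (inclusive)
#'   restricting both detections and deployment days.
#' @return A tibble: `receiver_id`, `detections`, `days_deployed`, `rate`,
#'   `n_sharks`, plus the receiver's `distance_to_entrance_km`.
#' @export
usage_rates <- function(dets, receivers, period = NULL) {
  if (is.null(period)) {
    period <- c(min(as.Date(receivers$deploy_start)),
                max(as.Date(receivers$deploy_end)) - 1L)
  }
  period <- as.Date(period)
  det_date <- as.Date(dets$timestamp, tz = "UTC")
  in_period <- det_date >= period[1] & det_date <= period[2]
  d <- dets[in_period, , drop = FALSE]
  ids <- unique(receivers$receiver_id)
  rows <- lapply(ids, function(rid) {
    dep <- receivers[receivers$receiver_id == rid, , drop = FALSE]
    nd <- length(deployment_days(dep, period[1], period[2]))
    if (nd == 0L) return(NULL)
    di <- d[d$receiver_id == rid, , drop = FALSE]
    tibble::tibble(
      receiver_id = rid,
      detections = nrow(di),
      days_deployed = nd,
      rate = nrow(di) / nd,
      n_sharks = dplyr::n_distinct(di$tag_id),
      distance_to_entrance_km = dep$distance_to_entrance_km[1]
    )
  })
  dplyr::bind_rows(rows)
}

#' Spatial weight matrix for receiver locations
#'
#' Builds the weights used by the Gi* statistic from the 1-D along-thalweg
#' distances between receivers. The default kernel is inverse distance
#' (`1/d^power`, power 1); the self-weight — Gi* includes the focal
#' location — is set to `1/d_min^power` where `d_min` is the smallest
#' non-zero pairwise distance, so a location counts as much as its nearest
#' neighbour. A `fixed_band` kernel (weight 1 within `band_km`, else 0,
#' self-weight 1) is also available. Coincident receivers are treated as
#' lying `d_min` apart.
#'
#' @param distances_km Numeric vector of along-thalweg distances to the
#'   entrance, one per receiver.
#' @param kernel `"inverse_distance"` or `"fixed_band"`.
#' @param power Exponent for the inverse-distance kernel (default 1).
#' @param band_km Band radius for the fixed-band kernel.
#' @return A symmetric n x n matrix with positive diagonal.
#' @export
receiver_weights <- function(distances_km,
                             kernel = c("inverse_distance", "fixed_band"),
                             power = 1, band_km = 3) {
  kernel <- match.arg(kernel)
  n <- length(distances_km)
  if (n < 2L) stop("need at least 2 receivers", call. = FALSE)
  dmat <- abs(outer(distances_km, distances_km, "-"))
  nz <- dmat[dmat > 0]
  if (length(nz) == 0L) stop("all receivers are coincident", call. = FALSE)
  d_min <- min(nz)
  if (kernel == "inverse_distance") {
    dmat[dmat == 0] <- d_min  # includes the diagonal: self-weight 1/d_min^p
    W <- 1 / dmat^power
  } else {
    W <- (dmat <= band_km) * 1
    diag(W) <- 1
  }
  W
}

#' Getis-Ord Gi* statistic
#'
#' For values `x` (here detections per day deployed) and weights `W`, each
#' location's Gi* z-score measures whether the weighted sum of values
#' around (and including) it is higher or lower than expected under spatial
#' randomness:
#' \deqn{z_i = \frac{\sum_j w_{ij} x_j - \bar{x} \sum_j w_{ij}}
#'   {S \sqrt{\left(n \sum_j w_{ij}^2 - (\sum_j w_{ij})^2\right)/(n-1)}}}
#' with \eqn{\bar{x}} the global mean and \eqn{S} the global (population)
#' standard deviation. `z > cutoff` classifies a hotspot, `z < -cutoff` a
#' coldspot (default cutoff 1.96, the 5% two-sided normal point).
#'
#' A zero numerator yields z = 0 (so equal values, or uniform weights, give
#' an all-neutral classification); when the values have zero variance but a
#' non-degenerate numerator cannot arise, z is 0 throughout and a warning
#' notes the degenerate stratum. No multiple-testing correction is applied
#' (set `fdr = TRUE` to classify on Benjamini-Hochberg adjusted p-values).
#'
#' @param values Numeric vector of location values.
#' @param W Weight matrix from [receiver_weights()] (or any n x n matrix
#'   with finite non-negative entries).
#' @param cutoff Classification threshold on |z| (default 1.96).
#' @param fdr Apply a Benjamini-Hochberg correction before classifying.
#' @return A tibble: `z`, `category` (`hotspot`/`coldspot`/`neutral`).
#' @export
gi_star <- function(values, W, cutoff = 1.96, fdr = FALSE) {
  n <- length(values)
  if (n < 3L) stop("Gi* needs at least 3 locations", call. = FALSE)
  stopifnot(is.matrix(W), nrow(W) == n, ncol(W) == n, all(is.finite(W)))
  xbar <- mean(values)
  S <- sqrt(max(sum(values^2) / n - xbar^2, 0))
  Wi <- rowSums(W)
  S1i <- rowSums(W^2)
  num <- as.numeric(W %*% values) - xbar * Wi
  den_inner <- (n * S1i - Wi^2) / (n - 1)
  den <- S * sqrt(pmax(den_inner, 0))
  z <- ifelse(abs(num) < 1e-12, 0, ifelse(den > 0, num / den, NaN))
  if (any(is.nan(z))) {
    warning("degenerate Gi* denominator; affected locations set neutral",
            call. = FALSE)
  }
  if (S == 0 && any(abs(num) >= 1e-12)) {
    warning("zero variance in values; z undefined, classified neutral",
            call. = FALSE)
    z <- ifelse(abs(num) < 1e-12, 0, NaN)
  }
  if (fdr) {
    p <- 2 * stats::pnorm(-abs(z))
    p_adj <- stats::p.adjust(p, method = "BH")
    sig <- !is.na(p_adj) & p_adj < 2 * stats::pnorm(-cutoff)
    category <- ifelse(is.nan(z) | !sig, "neutral",
                       ifelse(z > 0, "hotspot", "coldspot"))
  } else {
    category <- ifelse(is.nan(z), "neutral",
                       ifelse(z > cutoff, "hotspot",
                              ifelse(z < -cutoff, "coldspot", "neutral")))
  }
  tibble::tibble(z = z, category = category)
}

#' Receiver hotspot classification, aggregate or per year
#'
#' Computes usage rates and the Gi* classification for the whole study
#' (`stratum = "aggregate"`) and, to expose inter-annual variability,
#' independently for each shark-year with at least `min_receivers` active
#' receivers (years with fewer are skipped with a warning).
#'
#' @param dets Detection tibble.
#' @param receivers Receiver deployment tibble.
#' @param cal A [study_calendar()]; shark-years partition the study.
#' @param kernel,power,band_km Passed to [receiver_weights()].
#' @param cutoff Passed to [gi_star()].
#' @param min_receivers Minimum active receivers per stratum (default 3).
#' @param per_year Also compute per-shark-year strata (default TRUE).
#' @return A tibble: `stratum`, `receiver_id`, `detections`,
#'   `days_deployed`, `rate`, `n_sharks`, `z`, `category`.
#' @export
hotspot_analysis <- function(dets, receivers, cal,
                             kernel = "inverse_distance", power = 1,
                             band_km = 3, cutoff = 1.96,
                             min_receivers = 3, per_year = TRUE) {
  stopifnot(inherits(cal, "study_calendar"))
  one_stratum <- function(label, period) {
    ur <- usage_rates(dets, receivers, period = period)
    if (is.null(ur) || nrow(ur) < min_receivers) {
      warning("stratum ", label, " has fewer than ", min_receivers,
              " active receivers; skipped", call. = FALSE)
      return(NULL)
    }
    W <- receiver_weights(ur$distance_to_entrance_km, kernel = kernel,
                          power = power, band_km = band_km)
    gi <- gi_star(ur$rate, W, cutoff = cutoff)
    dplyr::bind_cols(tibble::tibble(stratum = label), ur, gi)
  }
  out <- list(one_stratum("aggregate", NULL))
  if (per_year) {
    yrs <- sort(unique(shark_year(as.Date(dets$timestamp, tz = "UTC"), cal)))
    for (y in yrs) {
      period <- c(max(shark_year_start(y, cal), cal$study_start),
                  min(shark_year_start(y + 1L, cal) - 1L, cal$study_end))
      out[[length(out) + 1L]] <- one_stratum(as.character(y), period)
    }
  }
  dplyr::bind_rows(out)
}

#' Model-ready hotspot covariate table
#'
#' Joins per-stratum Gi* classifications onto receiver habitat covariates
#' (mean depth and maximum seabed slope within the effective detection
#' range), producing the rows for the binomial hotspot-habitat model. The
#' aggregate stratum is excluded; station identity is retained for the
#' random intercept. Rows with missing covariates are flagged.
#'
#' @param results Output of [hotspot_analysis()].
#' @param receivers Receiver tibble with `mean_depth_m` and `max_slope`.
#' @return A tibble: `receiver_id`, `year`, `is_hotspot` (0/1),
#'   `mean_depth_m`, `max_slope`, `covariates_missing`.
#' @export
hotspot_covariate_table <- function(results, receivers) {
  rec <- dplyr::distinct(receivers, .data$receiver_id, .data$mean_depth_m,
                         .data$max_slope)
  out <- results |>
    dplyr::filter(.data$stratum != "aggregate") |>
    dplyr::transmute(
      receiver_id = .data$receiver_id,
      year = .data$stratum,
      is_hotspot = as.integer(.data$category == "hotspot")
    ) |>
    dplyr::left_join(rec, by = "receiver_id") |>
    dplyr::mutate(covariates_missing = is.na(.data$mean_depth_m) |
                    is.na(.data$max_slope))
  out
}
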