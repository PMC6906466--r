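#' Daily presence/abundance table with environmental covariates
#'
#' One row per day of the modelling window (by default the intersection of
#' the environmental series and the deployment record): the number of
#' distinct animals with a presence day, whether any was present, the
#' number of receivers deployed, the number of animals tagged to date
#' (tag_date on or before the day — a monotone step function), and the
#' environmental covariates. Days without a water temperature (or without
#' a previous-day rainfall at the window boundary) are excluded and
#' counted in attribute `n_excluded`.
#'
#' @param presence Presence-day tibble from [presence_days()].
#' @param sharks Shark metadata tibble (`shark_id`, `tag_date`).
#' @param deployments Receiver deployment tibble.
#' @param env Daily environmental tibble (see [read_env_daily()]).
#' @param window Optional length-2 date vector overriding the default
#'   modelling window.
#' @return A tibble: `date`, `n_sharks_present`, `present`,
#'   `n_receivers_deployed`, `n_tagged_to_date`, `water_temp_c`,
#'   `rain_mm`, `rain_prev_mm`, `moon_frac`.
#' @export
build_daily_table <- function(presence, sharks, deployments, env,
                              window = NULL) {
  env <- env[order(env$date), ]
  if (!"rain_prev_mm" %in% names(env)) {
    env$rain_prev_mm <- c(NA_real_, utils::head(env$rain_mm, -1))
  }
  if (is.null(window)) {
    window <- c(max(min(env$date), min(as.Date(deployments$deploy_start))),
                min(max(env$date), max(as.Date(deployments$deploy_end)) - 1L))
  }
  window <- as.Date(window)
  days <- seq(window[1], window[2], by = "day")
  dep_days <- lapply(unique(deployments$receiver_id), function(rid) {
    deployment_days(deployments[deployments$receiver_id == rid, ],
                    window[1], window[2])
  })
  n_rec <- rowSums(vapply(dep_days, function(dd) days %in% dd,
                          logical(length(days))))
  pres_n <- presence |>
    dplyr::filter(.data$date >= window[1], .data$date <= window[2]) |>
    dplyr::count(.data$date, name = "n_sharks_present")
  tag_dates <- sort(as.Date(sharks$tag_date))
  out <- tibble::tibble(date = days) |>
    dplyr::left_join(pres_n, by = "date") |>
    dplyr::mutate(
      n_sharks_present = dplyr::coalesce(.data$n_sharks_present, 0L),
      present = as.integer(.data$n_sharks_present > 0),
      n_receivers_deployed = n_rec,
      n_tagged_to_date = findInterval(.data$date, tag_dates)
    ) |>
    dplyr::left_join(env, by = "date")
  bad <- is.na(out$water_temp_c) | is.na(out$rain_prev_mm)
  n_excluded <- sum(bad)
  out <- out[!bad, , drop = FALSE]
  if (any(out$n_sharks_present > out$n_tagged_to_date)) {
    stop("more animals present than tagged to date: presence days and ",
         "tag dates are inconsistent", call. = FALSE)
  }
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Environmental hurdle analysis of daily presence and abundance
#'
#' Fits the two-stage hurdle model with smooths of the environmental
#' covariates and the additive effort offset, then decides per-covariate
#' retention in each stage by drop-one comparison through [select_model()]
#' with a confirmatory twist: a covariate is retained only when the AICc
#' comparison favours keeping it *and* its approximate Wald p-value in the
#' full model is at most 0.05. Requiring both guards against the
#' anticonservatism of information-criterion screening when daily presence
#' is strongly seasonal (near-separated). The retained model is refitted
#' and partial-effect curves are emitted for its covariates.
#'
#' @param data Daily table from [build_daily_table()].
#' @param covariates Environmental covariate columns (default water
#'   temperature, moon illumination, same-day and previous-day rainfall).
#' @param k Basis size for each covariate smooth (default 6).
#' @param ... Passed to [fit_gam()].
#' @return A list of class `et_hurdle_analysis`: `fit` (the retained
#'   [fit_hurdle()] model), `retained` (list with `stage1`/`stage2`
#'   character vectors), `selection` (per-stage drop-one tables), and
#'   `partial_effects` (list of tibbles per stage and covariate).
#' @export
run_hurdle_analysis <- function(data,
                                covariates = c("water_temp_c", "moon_frac",
                                               "rain_mm", "rain_prev_mm"),
                                k = 6, ...) {
  smooth_for <- function(v) sm(v, bs = "cubic", k = k)
  stage_retention <- function(response, family) {
    fit_stage <- function(vars, fixed_lambda = NULL) {
      d <- if (family == "gamma") {
        data[data$n_sharks_present > 0, , drop = FALSE]
      } else data
      off <- additive_log_offset(d, c("n_receivers_deployed",
                                      "n_tagged_to_date"))
      fit_gam(d, response, family = family,
              smooths = lapply(vars, smooth_for), offset = off,
              fixed_lambda = fixed_lambda, ...)
    }
    full <- fit_stage(covariates)
    keep <- character()
    tables <- list()
    for (v in covariates) {
      # hold the shared smooths at the full model's smoothing parameters
      # so the comparison isolates the dropped term
      reduced <- fit_stage(setdiff(covariates, v),
                           fixed_lambda = full$lambdas)
      sel <- select_model(list(full, reduced),
                          labels = c("with", "without"))
      tables[[v]] <- sel$table
      # confirmatory retention: a covariate stays only when the AICc
      # comparison AND the approximate Wald test both support it
      p_v <- full$terms$p_value[full$terms$term == v]
      if (sel$best_label == "with" && length(p_v) == 1 && p_v <= 0.05) {
        keep <- c(keep, v)
      }
    }
    list(keep = keep, tables = tables)
  }
  s1 <- stage_retention("present", "binomial")
  s2 <- if (any(data$n_sharks_present > 0)) {
    stage_retention("n_sharks_present", "gamma")
  } else list(keep = character(), tables = list())

  union_keep <- union(s1$keep, s2$keep)
  final <- fit_hurdle(data,
                      smooths = lapply(union_keep, smooth_for), ...)
  pe <- list(stage1 = lapply(stats::setNames(s1$keep, s1$keep),
                             function(v) partial_effect(final$stage1, v)),
             stage2 = if (!is.null(final$stage2)) {
               lapply(stats::setNames(s2$keep, s2$keep), function(v) {
                 if (v %in% names(final$stage2$bases)) {
                   partial_effect(final$stage2, v)
                 } else NULL
               })
             } else list())
  structure(list(fit = final,
                 retained = list(stage1 = s1$keep, stage2 = s2$keep),
                 selection = list(stage1 = s1$tables, stage2 = s2$tables),
                 partial_effects = pe),
            class = "et_hurdle_analysis")
}

#' Hotspot-habitat model
#'
#' Binomial GAM of whether a receiver location classified as a hotspot in
#' a given year, against smooths of mean depth and maximum slope within
#' the effective detection range, a linear year term, and a station random
#' intercept for the repeated yearly measures. Year, depth and slope are
#' each subjected to the same drop-one AICc retention as the environmental
#' models. Quasi-complete separation (all hotspot rows in one covariate
#' stratum) is absorbed by the smoothing/ridge penalties; a warning is
#' raised when fitted probabilities pin to 0/1.
#'
#' @param covtab Covariate table from [hotspot_covariate_table()].
#' @param k Basis size for the depth and slope smooths (default 5).
#' @param ... Passed to [fit_gam()].
#' @return A list of class `et_hotspot_model`: `fit`, `retained`,
#'   `selection`, and `directions` — the sign of each retained smooth's
#'   partial effect from the low to the high end of its covariate
#'   (negative for depth means shallow sites are more likely hotspots).
#' @export
run_hotspot_model <- function(covtab, k = 5, ...) {
  covtab <- covtab[!covtab$covariates_missing, , drop = FALSE]
  covtab$year_num <- as.numeric(factor(covtab$year))
  multi_year <- length(unique(covtab$year)) > 1L
  cand_smooth <- c("mean_depth_m", "max_slope")
  fit_one <- function(vars, with_year, fixed_lambda = NULL) {
    fit_gam(covtab, "is_hotspot", family = "binomial",
            smooths = lapply(vars, function(v) sm(v, bs = "cubic", k = k)),
            linear = if (with_year && multi_year) "year_num" else character(),
            group = "receiver_id", fixed_lambda = fixed_lambda, ...)
  }
  full <- fit_one(cand_smooth, with_year = TRUE)
  keep <- character(); tables <- list()
  for (v in cand_smooth) {
    reduced <- fit_one(setdiff(cand_smooth, v), with_year = TRUE,
                       fixed_lambda = full$lambdas)
    sel <- select_model(list(full, reduced), labels = c("with", "without"))
    tables[[v]] <- sel$table
    if (sel$best_label == "with") keep <- c(keep, v)
  }
  year_kept <- FALSE
  if (multi_year) {
    no_year <- fit_one(cand_smooth, with_year = FALSE,
                       fixed_lambda = full$lambdas)
    sel <- select_model(list(full, no_year), labels = c("with", "without"))
    tables[["year"]] <- sel$table
    year_kept <- sel$best_label == "with"
  }
  final <- fit_one(keep, with_year = year_kept)
  if (any(final$fitted > 1 - 1e-6 | final$fitted < 1e-6)) {
    warning("fitted hotspot probabilities pinned to 0/1: separation ",
            "absorbed by the penalty", call. = FALSE)
  }
  directions <- vapply(cand_smooth, function(v) {
    pe <- partial_effect(if (v %in% names(final$bases)) final else full, v,
                         n = 25)
    sign(pe$fit[nrow(pe)] - pe$fit[1])
  }, numeric(1))
  structure(list(fit = final,
                 retained = c(keep, if (year_kept) "year_num"),
                 selection = tables, directions = directions),
            class = "et_hotspot_model")
}
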