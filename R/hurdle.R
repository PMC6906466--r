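#' Two-stage hurdle model of daily presence and abundance
#'
#' Stage 1 models the presence-absence of any animal on each day with a
#' binomial GAM; stage 2 models the number of animals present on the days
#' when at least one was present (abundance > 0) with a gamma GAM. Both
#' stages carry the same additive link-scale offset,
#' `log(n_receivers) + log(n_tagged)`, so that monitoring effort (receiver
#' coverage and the growing tagged population) acts multiplicatively on
#' expected counts and does not masquerade as an environmental effect.
#'
#' @param data Daily table (see [build_daily_table()]), one row per day.
#' @param smooths List of [sm()] specifications for the environmental
#'   covariates (shared by both stages).
#' @param linear Character vector of unpenalized linear terms.
#' @param presence_col Binary presence column (default `"present"`).
#' @param abundance_col Positive-count column (default
#'   `"n_sharks_present"`).
#' @param offset_cols Columns whose logs are summed into the offset
#'   (default receivers deployed and animals tagged to date).
#' @param min_positive Minimum positive days before stage 2 is considered
#'   stable (default 30; fewer flags the fit).
#' @param ... Passed to [fit_gam()] (e.g. `lambda_grid`).
#' @return A list of class `et_hurdle`: `stage1`, `stage2` (NULL when no
#'   positive days), `offset_cols`, `stage2_stable`.
#' @export
fit_hurdle <- function(data, smooths = list(), linear = character(),
                       presence_col = "present",
                       abundance_col = "n_sharks_present",
                       offset_cols = c("n_receivers_deployed",
                                       "n_tagged_to_date"),
                       min_positive = 30, ...) {
  off <- additive_log_offset(data, offset_cols)
  stage1 <- fit_gam(data, presence_col, family = "binomial",
                    smooths = smooths, linear = linear, offset = off, ...)
  pos <- data[data[[abundance_col]] > 0, , drop = FALSE]
  stage2 <- NULL
  stage2_stable <- FALSE
  if (nrow(pos) > 0L) {
    stopifnot(all(pos[[abundance_col]] > 0))  # hurdle stage separation
    off2 <- additive_log_offset(pos, offset_cols)
    stage2 <- fit_gam(pos, abundance_col, family = "gamma",
                      smooths = smooths, linear = linear, offset = off2, ...)
    stage2_stable <- nrow(pos) >= min_positive
    if (!stage2_stable) {
      warning("only ", nrow(pos), " positive days; the abundance stage ",
              "is flagged unstable", call. = FALSE)
    }
  }
  structure(list(stage1 = stage1, stage2 = stage2,
                 offset_cols = offset_cols,
                 stage2_stable = stage2_stable),
            class = "et_hurdle")
}

#' @export
print.et_hurdle <- function(x, ...) {
  cat("<et_hurdle>\nStage 1 (presence, binomial):\n")
  print(x$stage1)
  if (is.null(x$stage2)) {
    cat("Stage 2: absent (no positive days)\n")
  } else {
    cat("Stage 2 (abundance | >0, gamma",
        if (!x$stage2_stable) ", UNSTABLE" else "", "):\n", sep = "")
    print(x$stage2)
  }
  invisible(x)
}

# log(n_receivers) + log(n_tagged): the additive effort offset on the link
# scale.
additive_log_offset <- function(data, offset_cols) {
  off <- rep(0, nrow(data))
  for (cn in offset_cols) {
    v <- data[[cn]]
    if (is.null(v)) stop("offset column not found: ", cn, call. = FALSE)
    if (any(v <= 0)) {
      stop("offset column ", cn, " must be positive", call. = FALSE)
    }
    off <- off + log(v)
  }
  off
}
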