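# Shared helpers: tiny hand-built tables, and an independent brute-force
# Gi* oracle (plain loops over the published formula, deliberately coded
# apart from the production path).

toy_detections <- function(rows) {
  # rows: list of c(tag, receiver, timestamp[, depth])
  tibble::tibble(
    tag_id = vapply(rows, `[[`, "", 1),
    receiver_id = vapply(rows, `[[`, "", 2),
    timestamp = as.POSIXct(vapply(rows, `[[`, "", 3), tz = "UTC"),
    depth_m = vapply(rows, function(r) {
      if (length(r) >= 4) as.numeric(r[[4]]) else NA_real_
    }, numeric(1)),
    temp_c = NA_real_
  )
}

toy_receivers <- function(dist_km, depth = 10, slope = 0.1,
                          from = "2010-01-01", to = "2016-01-01") {
  n <- length(dist_km)
  tibble::tibble(
    receiver_id = sprintf("R%02d", seq_len(n)),
    lat = -33.85, lon = 151.2,
    distance_to_entrance_km = dist_km,
    mean_depth_m = rep_len(depth, n),
    max_depth_m = rep_len(depth, n) * 1.6,
    max_slope = rep_len(slope, n),
    deploy_start = as.Date(from),
    deploy_end = as.Date(to)
  )
}

gi_star_bruteforce <- function(x, W) {
  n <- length(x)
  xbar <- sum(x) / n
  S <- sqrt(sum(x * x) / n - xbar * xbar)
  z <- numeric(n)
  for (i in seq_len(n)) {
    sw <- 0; sw2 <- 0; swx <- 0
    for (j in seq_len(n)) {
      sw <- sw + W[i, j]
      sw2 <- sw2 + W[i, j]^2
      swx <- swx + W[i, j] * x[j]
    }
    num <- swx - xbar * sw
    den <- S * sqrt((n * sw2 - sw^2) / (n - 1))
    z[i] <- if (abs(num) < 1e-12) 0 else num / den
  }
  z
}
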