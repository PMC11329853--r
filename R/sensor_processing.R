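#' Decode a raw sensor log to a resistance series
#'
#' Parses the raw-capture CSV dialect (3 header lines: sensor id, trial id,
#' stream start timestamp; then `timestamp_iso8601,hex_resistance` rows),
#' converts the hexadecimal resistance fields to integer counts and scales
#' them to ohms, and generates the time vector linearly from the start
#' timestamp to the last sample timestamp with uniform spacing (per-sample
#' clock jitter is not trusted at millisecond log resolution).
#'
#' @param path Path to a sensor log.
#' @param ohm_per_count Count resolution, ohms.
#' @return List of class `"resistance_series"` with fields `sensor_id`,
#'   `trial_id`, `start_time` (POSIXct, UTC), `t` (seconds from stream start,
#'   strictly increasing), `r` (ohms), `counts`.
#' @export
decode_log <- function(path, ohm_per_count = LOG_OHM_PER_COUNT) {
  lines <- readLines(path)
  if (length(lines) < 4) stop("sensor log too short: ", path)
  hdr <- strsplit(lines[1:3], ",", fixed = TRUE)
  keys <- vapply(hdr, `[`, "", 1)
  if (!identical(keys, c("sensor_id", "trial_id", "start")))
    stop("malformed sensor log header in ", path)
  sensor_id <- as.integer(hdr[[1]][2])
  trial_id <- hdr[[2]][2]
  start_time <- parse_iso8601(hdr[[3]][2])

  body <- strsplit(lines[-(1:3)], ",", fixed = TRUE)
  nfield <- lengths(body)
  if (any(nfield != 2))
    stop("malformed record at line ", which(nfield != 2)[1] + 3, " of ", path)
  stamps <- vapply(body, `[`, "", 1)
  hex <- vapply(body, `[`, "", 2)
  bad <- grepl("[^0-9A-Fa-f]", hex) | hex == ""
  if (any(bad))
    stop("malformed hex field at line ", which(bad)[1] + 3, " of ", path)
  counts <- strtoi(hex, base = 16L)
  if (any(is.na(counts)))
    stop("unparseable hex field at line ", which(is.na(counts))[1] + 3,
         " of ", path)
  times <- parse_iso8601(stamps)
  rel <- as.numeric(difftime(times, start_time, units = "secs"))
  if (any(diff(rel) < 0))
    stop("non-monotone timestamps in ", path)
  n <- length(counts)
  # linear time vector from start to the last recorded timestamp
  t <- if (n > 1) seq(0, rel[n], length.out = n) else 0
  structure(list(sensor_id = sensor_id, trial_id = trial_id,
                 start_time = start_time, t = t,
                 r = counts * ohm_per_count, counts = counts),
            class = "resistance_series")
}

#' Derive the strain proxy from a resistance series
#'
#' Computes `eps(t) = (r(t) - R0) / R0`, the fractional resistance change,
#' optionally divided by the gauge factor K to give true strain
#' (`dR/R = K * eps`). When K is not supplied the proxy absorbs it; the
#' downstream trial normalization removes scale, so validity results are
#' identical either way. The baseline R0 is estimated from the trial's own
#' samples: mean of the first `baseline_window_s` seconds (robust to startup
#' noise) or the first sample.
#'
#' @param rs A `resistance_series` (possibly Hampel-filtered).
#' @param baseline_mode `"first_window"` or `"first_sample"`.
#' @param baseline_window_s Window for `"first_window"`, seconds.
#' @param gauge_factor Optional gauge factor K (> 0).
#' @return List of class `"strain_series"` with fields `sensor_id`,
#'   `trial_id`, `start_time`, `t`, `eps`, `baseline_r0`,
#'   `gauge_factor_used` (NA when absorbed).
#' @export
compute_strain <- function(rs, baseline_mode = c("first_window", "first_sample"),
                           baseline_window_s = 0.5, gauge_factor = NULL) {
  stopifnot(inherits(rs, "resistance_series"))
  if (length(rs$r) == 0) stop("empty resistance series")
  baseline_mode <- match.arg(baseline_mode)
  r0 <- switch(baseline_mode,
    first_window = {
      idx <- rs$t <= rs$t[1] + baseline_window_s
      mean(rs$r[idx])
    },
    first_sample = rs$r[1]
  )
  if (!is.finite(r0) || r0 <= 0) stop("baseline resistance must be positive")
  eps <- (rs$r - r0) / r0
  k <- NA_real_
  if (!is.null(gauge_factor)) {
    if (gauge_factor <= 0) stop("gauge_factor must be positive")
    eps <- eps / gauge_factor
    k <- gauge_factor
  }
  structure(list(sensor_id = rs$sensor_id, trial_id = rs$trial_id,
                 start_time = rs$start_time, t = rs$t, eps = eps,
                 baseline_r0 = r0, gauge_factor_used = k),
            class = "strain_series")
}

#' Hampel outlier filter
#'
#' Sliding-window outlier filter: sample i is replaced by its window median
#' when it deviates from that median by more than `n_mad` times the scaled
#' median absolute deviation (1.4826 x MAD, the Gaussian-consistent robust
#' scale) of the window. Edge samples use truncated windows, so the filter is
#' defined over the whole series.
#'
#' @param x Numeric series.
#' @param window_halfwidth Half-width of the sliding window in samples
#'   (window = 2 * halfwidth + 1); must be >= 1 and the full window must not
#'   exceed the series length.
#' @param n_mad Threshold in robust-scale units (> 0); 3 is the conventional
#'   Hampel identifier.
#' @return List with `x` (filtered series) and `outliers` (logical mask of
#'   replaced samples).
#' @export
hampel_filter <- function(x, window_halfwidth = 5, n_mad = 3) {
  if (window_halfwidth < 1) stop("window_halfwidth must be >= 1")
  if (n_mad <= 0) stop("n_mad must be positive")
  n <- length(x)
  if (2 * window_halfwidth + 1 > n)
    stop("window (", 2 * window_halfwidth + 1, ") longer than series (", n, ")")
  .hampel_core(as.numeric(x), as.integer(window_halfwidth), n_mad)
}

#' Hampel-filter the resistance of a series object
#' @param rs A `resistance_series`.
#' @inheritParams hampel_filter
#' @return The series with filtered `r` and an added `outliers` mask.
#' @export
hampel_filter_series <- function(rs, window_halfwidth = 5, n_mad = 3) {
  stopifnot(inherits(rs, "resistance_series"))
  f <- hampel_filter(rs$r, window_halfwidth, n_mad)
  rs$r <- f$x
  rs$counts <- NULL   # counts no longer reflect r
  rs$outliers <- f$outliers
  rs
}

#' Flag failed sensor streams by the population resistance rule
#'
#' A stream (one sensor in one trial) fails when its trial-mean resistance
#' lies more than `threshold_sd` standard deviations from the mean resistance
#' across participants for the same movement and sensor. Mean and SD for each
#' stream are computed from the other streams of its (movement, sensor) group
#' (leave-one-out), so a single grossly failed sensor cannot mask itself by
#' inflating the group SD. Groups with a single stream are never flagged (SD
#' undefined) and raise a warning.
#'
#' @param stats Data frame with one row per stream and columns
#'   `participant_id`, `movement`, `sensor_id`, `statistic` (trial-mean
#'   resistance, ohms).
#' @param threshold_sd Threshold in SD units (default 10).
#' @return Data frame of class `"qc_report"`: the input plus
#'   `population_mean`, `population_sd`, `threshold_sd`, `flagged`; attributes
#'   `n_flagged` and `removal_fraction`.
#' @export
flag_failed_streams <- function(stats, threshold_sd = 10) {
  need <- c("participant_id", "movement", "sensor_id", "statistic")
  if (!all(need %in% names(stats)))
    stop("stats must have columns ", paste(need, collapse = ", "))
  n <- nrow(stats)
  pm <- rep(NA_real_, n); ps <- rep(NA_real_, n); fl <- rep(FALSE, n)
  key <- interaction(stats$movement, stats$sensor_id, drop = TRUE)
  for (g in levels(key)) {
    idx <- which(key == g)
    if (length(idx) < 2) {
      warning("group ", g, " has a single stream; SD undefined, nothing flagged")
      next
    }
    for (i in idx) {
      others <- stats$statistic[setdiff(idx, i)]
      pm[i] <- mean(others)
      ps[i] <- stats::sd(others)
      if (is.na(ps[i])) next   # only one other stream: SD undefined, keep
      fl[i] <- abs(stats$statistic[i] - pm[i]) > threshold_sd * ps[i]
    }
  }
  out <- stats
  out$population_mean <- pm
  out$population_sd <- ps
  out$threshold_sd <- threshold_sd
  out$flagged <- fl
  attr(out, "n_flagged") <- sum(fl)
  attr(out, "removal_fraction") <- sum(fl) / n
  class(out) <- c("qc_report", class(out))
  out
}
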