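#' Zero-phase-shift cross-correlation coefficient
#'
#' `r0 = sum(x * y) / sqrt(sum(x^2) * sum(y^2))`: the cross-correlation
#' sequence at lag 0 under coefficient normalization (no demeaning), the
#' quantity the validity analysis is built on. Bounded in [-1, 1] by
#' Cauchy-Schwarz; invariant to positive rescaling of either argument and
#' symmetric in its arguments. A demeaned (Pearson) variant is available via
#' `demean = TRUE` and is reported alongside in pipeline outputs.
#'
#' @param x,y Equal-length numeric series.
#' @param demean Subtract means first (Pearson-style)?
#' @return Single numeric in [-1, 1], or `NA` if either series has zero
#'   energy.
#' @export
zero_lag_xcorr <- function(x, y, demean = FALSE) {
  if (length(x) != length(y)) stop("series must have equal length")
  if (demean) {
    x <- x - mean(x)
    y <- y - mean(y)
  }
  ex <- sum(x^2)
  ey <- sum(y^2)
  if (ex == 0 || ey == 0) return(NA_real_)
  sum(x * y) / sqrt(ex * ey)
}

#' Cross-correlation profile over lags
#'
#' Coefficient-normalized cross-correlation at integer sample lags; lag 0
#' equals [zero_lag_xcorr()]. Secondary output only: the validity analysis
#' uses lag 0.
#'
#' @param x,y Equal-length numeric series.
#' @param max_lag Largest lag, samples.
#' @return Data frame with columns `lag` and `r`.
#' @export
xcorr_profile <- function(x, y, max_lag = length(x) - 1) {
  n <- length(x)
  if (length(y) != n) stop("series must have equal length")
  denom <- sqrt(sum(x^2) * sum(y^2))
  if (denom == 0) stop("zero-energy series")
  lags <- seq(-max_lag, max_lag)
  # positive lag: y is displaced later than x
  r <- vapply(lags, function(L) {
    if (L >= 0) sum(x[seq_len(n - L)] * y[seq_len(n - L) + L])
    else sum(x[seq_len(n + L) - L] * y[seq_len(n + L)])
  }, numeric(1))
  data.frame(lag = lags, r = r / denom)
}

#' Sensor-to-reference-angle map
#'
#' Which lumbar angle each tape is validated against: the upper and middle
#' tapes (sensors 1-4) against the upper lumbar angle, the lower tapes
#' (sensors 5 and 6) against the lower lumbar angle.
#'
#' @return Named character vector indexed by sensor id ("1".."6").
#' @export
sensor_reference_map <- function() {
  c(`1` = "upper_lumbar", `2` = "upper_lumbar",
    `3` = "upper_lumbar", `4` = "upper_lumbar",
    `5` = "lower_lumbar", `6` = "lower_lumbar")
}

#' Evaluate one sensor trial against its mapped reference angle
#'
#' @param pair An `aligned_pair` from [normalize_pair()].
#' @param sensor_id Sensor number 1-6.
#' @param map Sensor-to-angle map, see [sensor_reference_map()].
#' @return List with `r0` (NA when the pair is degenerate), `r0_demeaned`,
#'   `interpretation` (`"tension"` if r0 > 0 else `"compression"`, NA when
#'   degenerate), and `reference_angle`.
#' @export
evaluate_trial <- function(pair, sensor_id, map = sensor_reference_map()) {
  stopifnot(inherits(pair, "aligned_pair"))
  key <- as.character(sensor_id)
  if (!key %in% names(map))
    stop("sensor ", sensor_id, " is not in the sensor-to-angle map")
  if (isTRUE(attr(pair, "degenerate")))
    return(list(r0 = NA_real_, r0_demeaned = NA_real_,
                interpretation = NA_character_,
                reference_angle = unname(map[key])))
  r0 <- zero_lag_xcorr(pair$eps_norm, pair$angle_norm)
  list(r0 = r0,
       r0_demeaned = zero_lag_xcorr(pair$eps_norm, pair$angle_norm, demean = TRUE),
       interpretation = if (is.na(r0)) NA_character_
                        else if (r0 > 0) "tension" else "compression",
       reference_angle = unname(map[key]))
}

#' Aggregate per-trial coefficients into the validity table
#'
#' Median, minimum, and maximum zero-lag coefficient per (movement, sensor)
#' cell across participants, with missing (QC-flagged or degenerate) trials
#' counted but never imputed.
#'
#' @param rows Data frame with one row per (participant, movement, sensor):
#'   columns `participant_id`, `movement`, `sensor_id`, `r0` (NA = missing).
#' @return Data frame of class `"validity_table"`: `movement`, `sensor_id`,
#'   `median_r0`, `min_r0`, `max_r0`, `n`, `n_missing`.
#' @export
aggregate_validity <- function(rows) {
  need <- c("participant_id", "movement", "sensor_id", "r0")
  if (!all(need %in% names(rows)))
    stop("rows must have columns ", paste(need, collapse = ", "))
  cells <- unique(rows[, c("movement", "sensor_id")])
  cells <- cells[order(match(cells$movement, movement_levels()),
                       cells$sensor_id), ]
  out <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    sub <- rows[rows$movement == cells$movement[i] &
                rows$sensor_id == cells$sensor_id[i], ]
    ok <- !is.na(sub$r0)
    data.frame(movement = cells$movement[i],
               sensor_id = cells$sensor_id[i],
               median_r0 = if (any(ok)) stats::median(sub$r0[ok]) else NA_real_,
               min_r0 = if (any(ok)) min(sub$r0[ok]) else NA_real_,
               max_r0 = if (any(ok)) max(sub$r0[ok]) else NA_real_,
               n = sum(ok),
               n_missing = sum(!ok))
  }))
  rownames(out) <- NULL
  class(out) <- c("validity_table", class(out))
  out
}

#' Heatmap of the validity table
#'
#' Movement-by-sensor matrix of median zero-lag cross-correlation, colored
#' green for positive coefficients (tape tension with the kinematic angle),
#' yellow for negative (compression), white near zero, and gray for cells with
#' no valid trials.
#'
#' @param summary A `validity_table` from [aggregate_validity()].
#' @return A ggplot object.
#' @export
plot_validity_heatmap <- function(summary) {
  df <- as.data.frame(summary)
  df$movement <- factor(df$movement, levels = rev(movement_levels()))
  df$sensor <- factor(df$sensor_id, levels = 1:6)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sensor, y = .data$movement,
                                   fill = .data$median_r0)) +
    ggplot2::geom_tile(color = "white") +
    ggplot2::geom_text(ggplot2::aes(
      label = ifelse(is.na(.data$median_r0), "n/a",
                     sprintf("%.2f", .data$median_r0))), size = 3) +
    ggplot2::scale_fill_gradient2(low = "goldenrod2", mid = "white",
                                  high = "forestgreen", midpoint = 0,
                                  limits = c(-1, 1), na.value = "gray80",
                                  name = "median r0") +
    ggplot2::labs(x = "sensor", y = NULL,
                  title = "Median zero-lag cross-correlation, strain vs kinematic angle") +
    ggplot2::theme_minimal()
}
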