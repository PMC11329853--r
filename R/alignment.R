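#' Align strain and kinematic series on a common absolute clock and trim
#'
#' Expresses both series in seconds on the motion-capture clock using the
#' per-trial stream-start timestamps, then crops both to the overlapping
#' interval so start and end times are identical.
#'
#' @param strain A `strain_series` (see [compute_strain()]).
#' @param angles A `kinematic_angles` data frame.
#' @param strain_start,angles_start Stream-start times: `POSIXct`, or numeric
#'   seconds on a shared clock.
#' @return List with `strain` and `angles`, both with `t` in seconds since the
#'   mocap stream start, trimmed to the common window.
#' @export
align_and_trim <- function(strain, angles, strain_start, angles_start) {
  as_time <- function(x) {
    if (is.character(x)) parse_iso8601(x) else as.POSIXct(x, tz = "UTC")
  }
  offset <- as.numeric(difftime(as_time(strain_start), as_time(angles_start),
                                units = "secs"))
  ts <- strain$t + offset   # strain samples on the mocap clock
  ta <- angles$t
  lo <- max(min(ts), min(ta))
  hi <- min(max(ts), max(ta))
  if (lo >= hi)
    stop(sprintf("streams do not overlap: strain [%.3f, %.3f] vs kinematics [%.3f, %.3f] s",
                 min(ts), max(ts), min(ta), max(ta)))
  keep_s <- ts >= lo & ts <= hi
  keep_a <- ta >= lo & ta <= hi
  strain$t <- ts[keep_s]
  strain$eps <- strain$eps[keep_s]
  angles_out <- angles[keep_a, , drop = FALSE]
  list(strain = strain, angles = angles_out)
}

#' Resample aligned strain onto the kinematic time base
#'
#' Linearly interpolates the strain series onto the kinematic sample times
#' (default), or both series onto a uniform `target_rate_hz` grid spanning the
#' common window. Extrapolation beyond either series is refused: kinematic
#' samples outside the strain span are dropped from both.
#'
#' @param aligned Output of [align_and_trim()].
#' @param angle_column Which angle column to carry (see
#'   [primary_angle_column()]).
#' @param target_rate_hz Optional shared rate, Hz.
#' @return Data frame with columns `t`, `eps`, `angle` on a shared time base.
#' @export
resample_to_common_base <- function(aligned, angle_column,
                                    target_rate_hz = NULL) {
  strain <- aligned$strain
  angles <- aligned$angles
  if (!angle_column %in% names(angles))
    stop("unknown angle column: ", angle_column)
  if (is.null(target_rate_hz)) {
    tt <- angles$t
    inside <- tt >= min(strain$t) & tt <= max(strain$t)
    tt <- tt[inside]
    ang <- angles[[angle_column]][inside]
  } else {
    lo <- max(min(strain$t), min(angles$t))
    hi <- min(max(strain$t), max(angles$t))
    tt <- seq(lo, hi, by = 1 / target_rate_hz)
    ang <- stats::approx(angles$t, angles[[angle_column]], xout = tt)$y
  }
  if (length(tt) < 2) stop("no common samples after resampling")
  eps <- stats::approx(strain$t, strain$eps, xout = tt)$y
  data.frame(t = tt, eps = eps, angle = ang)
}

#' Normalize an aligned strain/angle pair for cross-correlation
#'
#' Strain: shifted so the movement starts at zero strain (initial value =
#' mean over the first `baseline_window_s` of the trimmed trial), then divided
#' by its maximum absolute value so -1 is peak sensor compression and +1 peak
#' tension. Angle: divided by its maximum absolute value so -1/+1 are the
#' peak movement in each direction, then multiplied by -1 for movements in
#' `flip_set` so the primary movement direction is positive for every
#' movement. A series whose maximum absolute value is below `degenerate_tol`
#' after shifting is flagged degenerate and left unscaled (excluded from
#' correlation downstream).
#'
#' @param pair Data frame from [resample_to_common_base()].
#' @param movement One of [movement_levels()].
#' @param flip_set Movements whose normalized angle is negated.
#' @param baseline_window_s Zero-strain shift estimation window, seconds.
#' @param degenerate_tol Zero-variance guard.
#' @return Data frame of class `"aligned_pair"` with columns `t`, `eps_norm`,
#'   `angle_norm`; attributes `movement` and `degenerate`.
#' @export
normalize_pair <- function(pair, movement, flip_set = default_flip_set(),
                           baseline_window_s = 0.25, degenerate_tol = 1e-12) {
  movement <- match.arg(movement, movement_levels())
  eps <- pair$eps
  idx <- pair$t <= pair$t[1] + baseline_window_s
  eps <- eps - mean(eps[idx])
  ang <- pair$angle
  degenerate <- FALSE
  m_eps <- max(abs(eps))
  m_ang <- max(abs(ang))
  if (m_eps < degenerate_tol || m_ang < degenerate_tol) {
    degenerate <- TRUE
  } else {
    eps <- eps / m_eps
    ang <- ang / m_ang
    if (movement %in% flip_set) ang <- -ang
  }
  out <- data.frame(t = pair$t, eps_norm = eps, angle_norm = ang)
  attr(out, "movement") <- movement
  attr(out, "degenerate") <- degenerate
  class(out) <- c("aligned_pair", class(out))
  out
}
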