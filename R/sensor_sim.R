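#' Sensor physics parameters
#'
#' Parameters of the piezoresistive tape model. The noiseless response is
#' `R(t) = R0 * (1 + d * trial_index) * (1 + K * eps_eff(t))` where `K` is the
#' gauge factor linking fractional resistance change to strain
#' (`dR/R = K * eps`), `d` is the fractional baseline rise per completed trial
#' (sensor fatigue), and `eps_eff` is the true skin strain clipped at
#' `+/- saturation_strain` plus a compression-release rebound transient:
#' after the strain crosses upward through `-rebound_trigger`, an additive
#' term `rebound_amplitude * exp(-dt / rebound_tau_s)` decays from the
#' crossing time. Gaussian resistance noise (SD `noise_sd`, ohms) and sparse
#' outlier spikes (probability `spike_rate` per sample, size
#' `spike_magnitude_mad` robust-scale units, random sign) are added on top.
#'
#' Defaults describe a realistic mid-session sensor; use
#' [ideal_sensor_physics()] for a noiseless, artifact-free sensor.
#'
#' @param baseline_resistance_ohm Resistance at zero strain, ohms (> 0).
#' @param gauge_factor Gauge factor K (> 0), dimensionless.
#' @param noise_sd Gaussian resistance noise SD per sample, ohms.
#' @param spike_rate Probability per sample of an outlier spike.
#' @param spike_magnitude_mad Spike size in robust-scale units (multiples of
#'   `1.4826 * noise_sd`, floored at 0.1% of baseline so spikes exist even for
#'   noiseless sensors).
#' @param saturation_strain Strain magnitude beyond which the film's response
#'   clips; `Inf` disables saturation.
#' @param fatigue_drift_per_trial Fractional baseline increase per completed
#'   trial.
#' @param rebound_amplitude Peak strain-equivalent of the post-compression
#'   rebound transient.
#' @param rebound_tau_s Rebound decay time constant, seconds.
#' @param rebound_trigger Strain threshold; release events fire when true
#'   strain crosses upward through `-rebound_trigger`.
#' @return List of class `"sensor_physics"`.
#' @export
sensor_physics <- function(baseline_resistance_ohm = 2000,
                           gauge_factor = 5,
                           noise_sd = 2,
                           spike_rate = 0.002,
                           spike_magnitude_mad = 20,
                           saturation_strain = 0.25,
                           fatigue_drift_per_trial = 0.01,
                           rebound_amplitude = 0.02,
                           rebound_tau_s = 0.5,
                           rebound_trigger = 0.01) {
  p <- list(baseline_resistance_ohm = baseline_resistance_ohm,
            gauge_factor = gauge_factor,
            noise_sd = noise_sd,
            spike_rate = spike_rate,
            spike_magnitude_mad = spike_magnitude_mad,
            saturation_strain = saturation_strain,
            fatigue_drift_per_trial = fatigue_drift_per_trial,
            rebound_amplitude = rebound_amplitude,
            rebound_tau_s = rebound_tau_s,
            rebound_trigger = rebound_trigger)
  num <- vapply(p, function(v) is.numeric(v) && length(v) == 1L, logical(1))
  if (!all(num)) stop("all sensor physics fields must be single numerics")
  if (baseline_resistance_ohm <= 0) stop("baseline_resistance_ohm must be > 0")
  if (gauge_factor <= 0) stop("gauge_factor must be > 0")
  if (any(unlist(p) < 0)) stop("sensor physics fields must be non-negative")
  structure(p, class = "sensor_physics")
}

#' Noiseless, artifact-free sensor physics
#' @inheritParams sensor_physics
#' @return A [sensor_physics()] object with noise, spikes, saturation, fatigue,
#'   and rebound all disabled.
#' @export
ideal_sensor_physics <- function(baseline_resistance_ohm = 2000,
                                 gauge_factor = 5) {
  sensor_physics(baseline_resistance_ohm = baseline_resistance_ohm,
                 gauge_factor = gauge_factor,
                 noise_sd = 0, spike_rate = 0, spike_magnitude_mad = 0,
                 saturation_strain = Inf, fatigue_drift_per_trial = 0,
                 rebound_amplitude = 0, rebound_tau_s = 0.5,
                 rebound_trigger = 0.01)
}

#' Effective strain seen by the sensing element
#'
#' Applies saturation clipping and the compression-release rebound transient
#' to a true skin-strain series. Deterministic.
#'
#' @param eps True strain series.
#' @param t Time vector, seconds (same length as `eps`).
#' @param physics A [sensor_physics()] object.
#' @return Effective strain series.
#' @export
effective_strain <- function(eps, t, physics) {
  stopifnot(length(eps) == length(t))
  eff <- pmin(pmax(eps, -physics$saturation_strain), physics$saturation_strain)
  if (physics$rebound_amplitude > 0 && length(eps) > 1) {
    trig <- -physics$rebound_trigger
    crossing <- which(eps[-length(eps)] < trig & eps[-1] >= trig) + 1L
    for (i in crossing) {
      idx <- seq(i, length(t))
      eff[idx] <- eff[idx] +
        physics$rebound_amplitude * exp(-(t[idx] - t[i]) / physics$rebound_tau_s)
    }
  }
  eff
}

#' Simulate raw sensor resistance for a strain series
#'
#' Forward model of the tape: gauge-factor response on the effective strain,
#' fatigue-scaled baseline, Gaussian noise, and sparse spikes. Uses the
#' current RNG stream; seed externally for reproducibility.
#'
#' @inheritParams effective_strain
#' @param trial_index Zero-based index of the trial within the session (drives
#'   fatigue drift).
#' @return Resistance series, ohms (not yet quantized).
#' @export
simulate_resistance <- function(eps, t, physics, trial_index = 0) {
  if (any(!is.finite(eps))) stop("strain series must be finite")
  if (trial_index < 0) stop("trial_index must be >= 0")
  eff <- effective_strain(eps, t, physics)
  r0 <- physics$baseline_resistance_ohm *
    (1 + physics$fatigue_drift_per_trial * trial_index)
  r <- r0 * (1 + physics$gauge_factor * eff)
  if (physics$noise_sd > 0)
    r <- r + stats::rnorm(length(r), sd = physics$noise_sd)
  if (physics$spike_rate > 0 && physics$spike_magnitude_mad > 0) {
    hit <- stats::runif(length(r)) < physics$spike_rate
    if (any(hit)) {
      scale <- max(1.4826 * physics$noise_sd,
                   1e-3 * physics$baseline_resistance_ohm)
      r[hit] <- r[hit] + physics$spike_magnitude_mad * scale *
        sample(c(-1, 1), sum(hit), replace = TRUE)
    }
  }
  if (any(r < 0))
    stop("simulated resistance went negative; physics parameters inconsistent")
  r
}

#' Resistance count resolution of the log dialect (ohms per count)
#' @export
LOG_OHM_PER_COUNT <- 0.1

#' Quantize resistance to integer log counts
#' @param r Resistance, ohms.
#' @param ohm_per_count Resolution, ohms per count.
#' @return Integer-valued numeric counts.
#' @export
quantize_resistance <- function(r, ohm_per_count = LOG_OHM_PER_COUNT) {
  round(r / ohm_per_count)
}

#' Encode integer counts as uppercase hexadecimal strings
#' @param counts Non-negative integer-valued numerics.
#' @return Character vector of hex strings.
#' @export
encode_hex <- function(counts) {
  if (any(counts < 0)) stop("cannot hex-encode negative counts")
  toupper(as.hexmode(as.integer(round(counts))))
}

#' Simulate one raw sensor log
#'
#' Runs [simulate_resistance()], quantizes to log counts, and assembles the
#' record structure written by [write_sensor_log()]: ISO 8601 timestamps and
#' hex-encoded resistance counts under a 3-line header (sensor id, trial id,
#' stream start timestamp).
#'
#' @inheritParams simulate_resistance
#' @param start_time `POSIXct` stream start (UTC recommended); sample `i`
#'   carries timestamp `start_time + t[i] - t[1]`.
#' @param sensor_id Sensor number 1-6.
#' @param trial_id Character trial identifier.
#' @return List of class `"sensor_log"` with fields `sensor_id`, `trial_id`,
#'   `start_time`, `t` (seconds from stream start), `counts`, `hex`.
#' @export
simulate_sensor_log <- function(eps, t, physics, trial_index,
                                start_time, sensor_id, trial_id) {
  r <- simulate_resistance(eps, t, physics, trial_index)
  counts <- quantize_resistance(r)
  structure(list(sensor_id = as.integer(sensor_id),
                 trial_id = as.character(trial_id),
                 start_time = start_time,
                 t = t - t[1],
                 counts = counts,
                 hex = encode_hex(counts)),
            class = "sensor_log")
}

format_iso8601 <- function(time) {
  format(time, "%Y-%m-%dT%H:%M:%OS3Z", tz = "UTC")
}

parse_iso8601 <- function(x) {
  out <- as.POSIXct(sub("Z$", "", x), format = "%Y-%m-%dT%H:%M:%OS", tz = "UTC")
  if (any(is.na(out))) stop("unparseable ISO 8601 timestamp: ",
                            x[which(is.na(out))[1]])
  out
}

#' Write a sensor log in the raw-capture CSV dialect
#'
#' Three header lines (`sensor_id`, `trial_id`, `start`) followed by
#' `timestamp_iso8601,hex_resistance` data rows.
#'
#' @param log A `sensor_log` from [simulate_sensor_log()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sensor_log <- function(log, path) {
  stopifnot(inherits(log, "sensor_log"))
  stamps <- format_iso8601(log$start_time + log$t)
  lines <- c(
    paste0("sensor_id,", log$sensor_id),
    paste0("trial_id,", log$trial_id),
    paste0("start,", format_iso8601(log$start_time)),
    paste(stamps, log$hex, sep = ",")
  )
  writeLines(lines, path)
  invisible(path)
}

#' Default sensor-to-strain gain map
#'
#' Signed gain mapping the normalized reference angle (0-1 over a trial) to
#' true skin strain for each (sensor, movement) pair. Sensors are laid out in
#' a 3 x 2 matrix just lateral to the spine: 1/2 upper (left/right), 3/4
#' middle, 5/6 lower. The default pattern follows the validation study's
#' observed tension/compression behaviour: flexion stretches the skin over all
#' sensors (tension, +); extension compresses it (-); lateral bending
#' stretches the contralateral side and compresses the ipsilateral side; axial
#' rotation stretches both upper sensors and the ipsilateral middle sensor,
#' with contralateral-middle and lower sensors showing no consistent response
#' (gain 0).
#'
#' @param magnitude Peak skin strain at full end range (dimensionless);
#'   default 0.15, a realistic lumbar skin strain at end-range movement.
#' @return Data frame with columns `sensor_id`, `movement`, `gain`.
#' @export
default_gain_map <- function(magnitude = 0.15) {
  m <- magnitude
  left <- c(1, 3, 5); right <- c(2, 4, 6)
  rows <- list()
  add <- function(sensors, movement, gain)
    data.frame(sensor_id = sensors, movement = movement, gain = gain)
  rows <- rbind(
    add(1:6, "forward_flexion", +m),
    add(1:6, "extension", -m),
    add(right, "left_lateral_bend", +m),
    add(left,  "left_lateral_bend", -m),
    add(left,  "right_lateral_bend", +m),
    add(right, "right_lateral_bend", -m),
    add(c(1, 2), "left_rotation", +m),
    add(3, "left_rotation", +m),
    add(c(4, 5, 6), "left_rotation", 0),
    add(c(1, 2), "right_rotation", +m),
    add(4, "right_rotation", +m),
    add(c(3, 5, 6), "right_rotation", 0)
  )
  rows <- rows[order(match(rows$movement, movement_levels()), rows$sensor_id), ]
  rownames(rows) <- NULL
  rows
}

#' Look up a gain in a gain map
#' @param gain_map Data frame from [default_gain_map()].
#' @param sensor_id Sensor number.
#' @param movement Movement name.
#' @return Single numeric gain.
#' @export
lookup_gain <- function(gain_map, sensor_id, movement) {
  hit <- gain_map$sensor_id == sensor_id & gain_map$movement == movement
  if (sum(hit) != 1) stop("gain map must contain exactly one entry for sensor ",
                          sensor_id, ", movement ", movement)
  gain_map$gain[hit]
}
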