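#' Scenario configuration for the synthetic study generator
#'
#' Bundles everything [generate_scenario()] needs to emulate the validation
#' study: cohort size, movement protocol, sensor physics, sensor gain map,
#' sampling rates, stream-start offset, and seed. Defaults reproduce the study
#' conditions: 10 participants, the six-movement protocol, 179 Hz motion
#' capture, and six tapes per participant. The sensor sampling rate is not
#' part of the study description; 50 Hz is a plausible rate for the described
#' Bluetooth link and deliberately differs from the mocap rate so resampling
#' is exercised.
#'
#' @param n_participants Number of participants (>= 1).
#' @param protocol List of [protocol_entry()] objects.
#' @param physics A [sensor_physics()] object.
#' @param gain_map Gain map data frame (see [default_gain_map()]).
#' @param mocap_rate_hz Motion-capture sampling rate, Hz.
#' @param sensor_rate_hz Sensor sampling rate, Hz.
#' @param rep_duration_s Duration of one movement repetition, seconds.
#' @param stream_offset_s Known offset of the sensor stream start after the
#'   mocap stream start, seconds; nonzero so timestamp alignment is
#'   nontrivially exercised.
#' @param shares Angle shares of the lower (relative to pelvis) and upper
#'   (relative to lower) lumbar joints.
#' @param geometry Nominal marker geometry.
#' @param marker_noise_mm RMS 3D marker noise, mm.
#' @param seed Integer seed; the full dataset is a deterministic function of
#'   the configuration including the seed.
#' @return List of class `"scenario_config"`.
#' @export
scenario_config <- function(n_participants = 10,
                            protocol = default_protocol(),
                            physics = sensor_physics(),
                            gain_map = default_gain_map(),
                            mocap_rate_hz = 179,
                            sensor_rate_hz = 50,
                            rep_duration_s = 3,
                            stream_offset_s = 0.5,
                            shares = c(lower = 0.5, upper = 0.5),
                            geometry = default_marker_geometry(),
                            marker_noise_mm = 0,
                            seed = 1L) {
  if (n_participants < 1) stop("n_participants must be >= 1")
  if (mocap_rate_hz <= 0 || sensor_rate_hz <= 0) stop("rates must be positive")
  stopifnot(inherits(physics, "sensor_physics"))
  stopifnot(all(vapply(protocol, inherits, logical(1), "protocol_entry")))
  structure(list(n_participants = as.integer(n_participants),
                 protocol = protocol, physics = physics, gain_map = gain_map,
                 mocap_rate_hz = mocap_rate_hz, sensor_rate_hz = sensor_rate_hz,
                 rep_duration_s = rep_duration_s,
                 stream_offset_s = stream_offset_s,
                 shares = shares, geometry = geometry,
                 marker_noise_mm = marker_noise_mm,
                 seed = as.integer(seed)),
            class = "scenario_config")
}

#' Generate a synthetic study dataset on disk
#'
#' Writes, for every participant x protocol entry: one marker TSV (motion
#' capture stream) and six sensor logs (one per tape), plus a JSON manifest
#' recording file paths, movement, trial index, and the start timestamp of
#' both streams. The sensor stream starts `stream_offset_s` after the mocap
#' stream and runs the same duration, so the two streams overlap on all but
#' the edges and alignment by start timestamps is required downstream. True
#' skin strain for sensor s is `gain(s, movement) * angle(t) / end_range`,
#' evaluated on the sensor's own clock. Bit-identical across runs with the
#' same configuration and seed.
#'
#' @param config A [scenario_config()].
#' @param out_dir Output directory (created if needed).
#' @return The manifest, invisibly (also written to `manifest.json`).
#' @export
generate_scenario <- function(config, out_dir) {
  stopifnot(inherits(config, "scenario_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)

  session_start <- as.POSIXct("2024-03-01 09:00:00", tz = "UTC")
  trials <- list()
  trial_counter <- 0L
  for (p in seq_len(config$n_participants)) {
    pid <- sprintf("P%02d", p)
    for (entry in config$protocol) {
      trial_counter <- trial_counter + 1L
      trial_index <- match(entry$movement, movement_levels()) - 1L
      trial_id <- sprintf("%s_%s", pid, entry$movement)
      prof_fun <- angle_profile_fun(entry, config$rep_duration_s)
      duration <- attr(prof_fun, "duration_s")
      mocap_start <- session_start + (trial_counter - 1) * ceiling(duration + 30)

      # mocap stream
      t_m <- seq(0, duration, by = 1 / config$mocap_rate_hz)
      angle_series <- data.frame(t = t_m, angle_deg = prof_fun(t_m))
      seq <- synthesize_marker_trajectories(
        angle_series, entry$movement, config$geometry, config$shares,
        marker_noise_mm = config$marker_noise_mm)
      marker_file <- file.path(out_dir, sprintf("%s_markers.tsv", trial_id))
      write_marker_tsv(seq, marker_file)

      # sensor streams: start offset after mocap, same duration
      off <- config$stream_offset_s
      t_s <- seq(off, off + duration, by = 1 / config$sensor_rate_hz)
      phi <- prof_fun(pmin(t_s, duration)) / entry$end_range_deg
      sensor_start <- mocap_start + off
      sensor_files <- character(6)
      for (s in 1:6) {
        gain <- lookup_gain(config$gain_map, s, entry$movement)
        log <- simulate_sensor_log(gain * phi, t_s, config$physics,
                                   trial_index = trial_index,
                                   start_time = sensor_start,
                                   sensor_id = s, trial_id = trial_id)
        sensor_files[s] <- file.path(out_dir,
                                     sprintf("%s_sensor%d.csv", trial_id, s))
        write_sensor_log(log, sensor_files[s])
      }

      trials[[trial_counter]] <- list(
        participant_id = pid,
        movement = entry$movement,
        trial_id = trial_id,
        trial_index = trial_index,
        end_range_deg = entry$end_range_deg,
        marker_file = basename(marker_file),
        sensor_files = basename(sensor_files),
        mocap_start = format_iso8601(mocap_start),
        sensor_start = format_iso8601(sensor_start),
        mocap_rate_hz = config$mocap_rate_hz,
        sensor_rate_hz = config$sensor_rate_hz
      )
    }
  }
  manifest <- list(
    seed = config$seed,
    n_participants = config$n_participants,
    stream_offset_s = config$stream_offset_s,
    trials = trials
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Read a scenario manifest
#' @param data_dir Directory containing `manifest.json`.
#' @return Manifest list.
#' @export
read_manifest <- function(data_dir) {
  path <- file.path(data_dir, "manifest.json")
  if (!file.exists(path)) stop("no manifest.json in ", data_dir)
  jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
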