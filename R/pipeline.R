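#' Run configuration
#'
#' Everything one reproducible pipeline run needs. Either `data_dir` points at
#' an existing dataset (marker TSVs + sensor logs + manifest) or `scenario`
#' requests simulation into `data_dir` first. Defaults mirror the study where
#' it states values (179 Hz motion capture, 10 SD quality-control threshold,
#' six sensors, six movements); invented values (Hampel parameters, baseline
#' windows) are documented at their functions.
#'
#' @param data_dir Dataset directory.
#' @param out_dir Output directory for artifacts.
#' @param scenario Optional [scenario_config()]; when given, the dataset is
#'   simulated into `data_dir` as the first stage.
#' @param threshold_sd Quality-control threshold, SD units.
#' @param hampel_halfwidth,hampel_nmad Hampel filter parameters.
#' @param flip_set Movements whose normalized angle is negated.
#' @param target_rate_hz Optional common resampling rate (default: kinematic
#'   time base).
#' @param baseline_window_s Baseline-resistance estimation window, seconds.
#' @param zero_shift_window_s Zero-strain shift estimation window, seconds.
#' @param demean Also report demeaned (Pearson) coefficients?
#' @param seed Seed recorded in the run report (the simulation seed lives in
#'   `scenario`).
#' @return List of class `"run_config"`.
#' @export
run_config <- function(data_dir, out_dir, scenario = NULL,
                       threshold_sd = 10,
                       hampel_halfwidth = 5, hampel_nmad = 3,
                       flip_set = default_flip_set(),
                       target_rate_hz = NULL,
                       baseline_window_s = 0.5,
                       zero_shift_window_s = 0.25,
                       demean = FALSE,
                       seed = 1L) {
  if (!is.null(scenario)) stopifnot(inherits(scenario, "scenario_config"))
  if (threshold_sd <= 0) stop("threshold_sd must be positive")
  structure(list(data_dir = data_dir, out_dir = out_dir, scenario = scenario,
                 threshold_sd = threshold_sd,
                 hampel_halfwidth = hampel_halfwidth,
                 hampel_nmad = hampel_nmad,
                 flip_set = flip_set, target_rate_hz = target_rate_hz,
                 baseline_window_s = baseline_window_s,
                 zero_shift_window_s = zero_shift_window_s,
                 demean = demean, seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Schema-validated: unknown keys are rejected. Nested `scenario` and
#' `scenario$physics` blocks are converted through [scenario_config()] and
#' [sensor_physics()] so their invariants are enforced.
#'
#' @param path YAML file.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- setdiff(names(formals(run_config)), "scenario")
  extra <- setdiff(names(raw), c(known, "scenario"))
  if (length(extra) > 0)
    stop("unknown config keys: ", paste(extra, collapse = ", "))
  scenario <- NULL
  if (!is.null(raw$scenario)) {
    sc <- raw$scenario
    known_sc <- names(formals(scenario_config))
    extra_sc <- setdiff(names(sc), known_sc)
    if (length(extra_sc) > 0)
      stop("unknown scenario keys: ", paste(extra_sc, collapse = ", "))
    if (!is.null(sc$physics)) sc$physics <- do.call(sensor_physics, sc$physics)
    if (!is.null(sc$shares)) sc$shares <- unlist(sc$shares)
    scenario <- do.call(scenario_config, sc)
  }
  args <- raw[intersect(names(raw), known)]
  args$scenario <- scenario
  do.call(run_config, args)
}

read_trial_strain <- function(trial, data_dir, config) {
  lapply(seq_along(trial$sensor_files), function(s) {
    rs <- decode_log(file.path(data_dir, trial$sensor_files[s]))
    rs <- hampel_filter_series(rs, config$hampel_halfwidth, config$hampel_nmad)
    rs
  })
}

#' Run the full validation pipeline
#'
#' Stages, in order: (optional) simulate the dataset; decode every sensor log
#' and Hampel-filter its resistance; flag failed streams by the population
#' quality-control rule; compute lumbar angles from every marker file; align,
#' resample, and normalize each retained sensor stream against its mapped
#' reference angle; compute zero-lag cross-correlations and aggregate the
#' validity table. Artifacts written under `config$out_dir`: per-trial
#' coefficients (`validity_long.csv`), the summary table
#' (`validity_summary.csv`), the QC report (`qc_report.csv`), a run report
#' (`run_report.json`), and the heatmap (`validity_heatmap.pdf`).
#'
#' @param config A [run_config()].
#' @param write_heatmap Write the heatmap PDF?
#' @return Run report list (also written as JSON): per-stage counts, QC
#'   summary, validity summary, and the effective configuration. The long
#'   table is attached as attribute `"rows"`, the summary as `"summary"`.
#' @export
run_pipeline <- function(config, write_heatmap = TRUE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  if (!is.null(config$scenario))
    generate_scenario(config$scenario, config$data_dir)
  manifest <- read_manifest(config$data_dir)
  trials <- manifest$trials

  # --- decode + filter all sensor streams
  streams <- list()
  for (tr in trials) {
    series <- read_trial_strain(tr, config$data_dir, config)
    for (rs in series) {
      key <- sprintf("%s|%d", tr$trial_id, rs$sensor_id)
      streams[[key]] <- list(trial = tr, rs = rs)
    }
  }
  n_decoded <- length(streams)

  # --- population QC on trial-mean resistance
  qc_stats <- do.call(rbind, lapply(streams, function(s) {
    data.frame(participant_id = s$trial$participant_id,
               movement = s$trial$movement,
               sensor_id = s$rs$sensor_id,
               statistic = mean(s$rs$r))
  }))
  rownames(qc_stats) <- NULL
  qc <- flag_failed_streams(qc_stats, config$threshold_sd)

  # --- kinematics per trial
  angles_by_trial <- list()
  required <- unlist(spine_model_definition(), use.names = FALSE)
  for (tr in trials) {
    seq <- read_marker_tsv(file.path(config$data_dir, tr$marker_file),
                           required_labels = required)
    if (anyNA(seq$positions)) seq <- interpolate_gaps(seq)
    angles_by_trial[[tr$trial_id]] <- compute_lumbar_angles(seq)
  }

  # --- align, normalize, correlate
  map <- sensor_reference_map()
  rows <- list()
  n_degenerate <- 0L
  for (key in names(streams)) {
    s <- streams[[key]]
    tr <- s$trial
    flagged <- qc$flagged[qc$participant_id == tr$participant_id &
                          qc$movement == tr$movement &
                          qc$sensor_id == s$rs$sensor_id]
    row <- data.frame(participant_id = tr$participant_id,
                      movement = tr$movement,
                      sensor_id = s$rs$sensor_id,
                      r0 = NA_real_, r0_demeaned = NA_real_,
                      interpretation = NA_character_,
                      reference_angle = unname(map[as.character(s$rs$sensor_id)]),
                      flagged = isTRUE(any(flagged)),
                      degenerate = FALSE)
    if (!row$flagged) {
      strain <- compute_strain(s$rs, baseline_window_s = config$baseline_window_s)
      angles <- angles_by_trial[[tr$trial_id]]
      aligned <- align_and_trim(strain, angles, tr$sensor_start, tr$mocap_start)
      col <- primary_angle_column(tr$movement, row$reference_angle)
      pair <- resample_to_common_base(aligned, col, config$target_rate_hz)
      pair <- normalize_pair(pair, tr$movement, config$flip_set,
                             config$zero_shift_window_s)
      res <- evaluate_trial(pair, s$rs$sensor_id, map)
      row$r0 <- res$r0
      row$r0_demeaned <- res$r0_demeaned
      row$interpretation <- res$interpretation
      row$degenerate <- isTRUE(attr(pair, "degenerate"))
      n_degenerate <- n_degenerate + row$degenerate
    }
    rows[[key]] <- row
  }
  rows <- do.call(rbind, rows)
  rownames(rows) <- NULL
  rows <- rows[order(match(rows$movement, movement_levels()),
                     rows$sensor_id, rows$participant_id), ]

  summary <- aggregate_validity(rows)

  # --- artifacts
  utils::write.csv(rows, file.path(config$out_dir, "validity_long.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(summary),
                   file.path(config$out_dir, "validity_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(qc), file.path(config$out_dir, "qc_report.csv"),
                   row.names = FALSE)
  if (write_heatmap) {
    p <- plot_validity_heatmap(summary)
    ggplot2::ggsave(file.path(config$out_dir, "validity_heatmap.pdf"), p,
                    width = 7, height = 4)
  }

  report <- list(
    stages = list(
      streams_decoded = n_decoded,
      streams_flagged = attr(qc, "n_flagged"),
      removal_fraction = attr(qc, "removal_fraction"),
      trials_correlated = sum(!is.na(rows$r0)),
      trials_degenerate = n_degenerate
    ),
    config = list(
      threshold_sd = config$threshold_sd,
      hampel_halfwidth = config$hampel_halfwidth,
      hampel_nmad = config$hampel_nmad,
      flip_set = config$flip_set,
      target_rate_hz = config$target_rate_hz,
      baseline_window_s = config$baseline_window_s,
      zero_shift_window_s = config$zero_shift_window_s,
      seed = config$seed,
      scenario_seed = if (!is.null(config$scenario)) config$scenario$seed else NULL
    ),
    summary = as.data.frame(summary)
  )
  jsonlite::write_json(report, file.path(config$out_dir, "run_report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  attr(report, "rows") <- rows
  attr(report, "summary") <- summary
  attr(report, "qc") <- qc
  report
}
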