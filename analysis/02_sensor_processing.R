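#!/usr/bin/env Rscript
# Stage 2 — decode sensor logs, filter outliers, quality-control streams.
#
# Decodes every hex-encoded resistance log to ohms, applies the Hampel filter
# (half-width 5 samples, 3 robust SDs), computes each stream's trial-mean
# resistance, and flags streams more than 10 SDs from the mean resistance
# across participants for the same movement and sensor. Writes per-stream
# strain series to scratch/strain/ and the QC report to results/.

suppressPackageStartupMessages(library(mtvalidate))

data_dir <- "scratch/dataset"
strain_dir <- "scratch/strain"
dir.create(strain_dir, recursive = TRUE, showWarnings = FALSE)
dir.create("results", showWarnings = FALSE)

manifest <- read_manifest(data_dir)
stats_rows <- list()
outlier_total <- 0L
for (tr in manifest$trials) {
  for (path in tr$sensor_files) {
    rs <- decode_log(file.path(data_dir, path))
    rs <- hampel_filter_series(rs)
    outlier_total <- outlier_total + sum(rs$outliers)
    st <- compute_strain(rs)
    utils::write.csv(
      data.frame(t = st$t, eps = st$eps),
      file.path(strain_dir, sub("\\.csv$", "_strain.csv", path)),
      row.names = FALSE)
    stats_rows[[paste(tr$trial_id, rs$sensor_id)]] <- data.frame(
      participant_id = tr$participant_id, movement = tr$movement,
      sensor_id = rs$sensor_id, statistic = mean(rs$r),
      baseline_r0 = st$baseline_r0)
  }
}
stats <- do.call(rbind, stats_rows)
qc <- flag_failed_streams(stats, threshold_sd = 10)
utils::write.csv(as.data.frame(qc), "results/qc_report.csv", row.names = FALSE)

cat(sprintf("decoded %d streams; Hampel replaced %d samples\n",
            nrow(qc), outlier_total))
cat(sprintf("QC flagged %d/%d streams (%.1f%%) at the 10 SD rule\n",
            attr(qc, "n_flagged"), nrow(qc),
            100 * attr(qc, "removal_fraction")))
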