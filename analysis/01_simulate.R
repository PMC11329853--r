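#!/usr/bin/env Rscript
# Stage 1 — simulate the synthetic validation study.
#
# Generates the default scenario: 10 participants, six low back movements
# (forward flexion, extension, left/right lateral bend, left/right seated
# rotation), 179 Hz motion capture, six tapes per participant sampled at
# 50 Hz with realistic sensor physics (noise, spikes, saturation, fatigue,
# rebound). Writes marker TSVs, hex-encoded sensor logs, and the manifest.

suppressPackageStartupMessages(library(mtvalidate))

data_dir <- "scratch/dataset"
cfg <- scenario_config(n_participants = 10, seed = 20240301)
manifest <- generate_scenario(cfg, data_dir)

n_trials <- length(manifest$trials)
cat(sprintf("simulated %d trials (%d participants x %d movements) into %s\n",
            n_trials, cfg$n_participants, length(cfg$protocol), data_dir))
cat(sprintf("  %d sensor logs, %d marker files, stream offset %.2f s\n",
            n_trials * 6, n_trials, cfg$stream_offset_s))
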