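test_that("zero angle series leaves all markers at nominal positions", {
  prof <- data.frame(t = seq(0, 1, by = 0.1), angle_deg = 0)
  seq <- synthesize_marker_trajectories(prof, "forward_flexion")
  geom <- default_marker_geometry()
  for (lab in rownames(geom)) {
    for (i in seq_along(prof$t))
      expect_equal(unname(seq$positions[i, , lab]), unname(geom[lab, ]),
                   tolerance = 1e-12)
  }
})

test_that("within-segment marker distances are constant over time (rigidity)", {
  prof <- generate_angle_profile(tiny_entry(end_range = 35), 60, 1.5)
  for (m in c("forward_flexion", "left_lateral_bend", "right_rotation")) {
    seq <- synthesize_marker_trajectories(prof, m)
    for (set in segment_marker_sets()) {
      pairs <- utils::combn(set, 2)
      for (j in seq_len(ncol(pairs))) {
        d <- sqrt(rowSums((seq$positions[, , pairs[1, j]] -
                           seq$positions[, , pairs[2, j]])^2))
        expect_lt(max(abs(d - d[1])), 1e-9)
      }
    }
  }
})

test_that("forward model and kinematics module are mutually inverse", {
  prof <- data.frame(t = seq(0, 2, by = 0.02),
                     angle_deg = 10 * sin(pi * seq(0, 2, by = 0.02) / 2)^2)
  seq <- synthesize_marker_trajectories(prof, "forward_flexion",
                                        shares = c(lower = 0.5, upper = 0.5))
  ang <- compute_lumbar_angles(seq)
  # flexion is the convention-negative X direction; each joint takes half
  expect_lt(max(abs(ang$upper_x - (-0.5 * prof$angle_deg))), 1e-6)
  expect_lt(max(abs(ang$lower_x - (-0.5 * prof$angle_deg))), 1e-6)
  expect_lt(max(abs(ang$upper_y)), 1e-6)
  expect_lt(max(abs(ang$upper_z)), 1e-6)
})

test_that("missing markers in the geometry raise a configuration error", {
  prof <- data.frame(t = 0, angle_deg = 0)
  geom <- default_marker_geometry()
  geom <- geom[rownames(geom) != "L3", ]
  expect_error(synthesize_marker_trajectories(prof, "forward_flexion", geom),
               "L3")
})

test_that("noiseless sensor simulation follows the gauge-factor law exactly", {
  phys <- sensor_physics(baseline_resistance_ohm = 1000, gauge_factor = 1,
                         noise_sd = 0, spike_rate = 0,
                         saturation_strain = Inf,
                         fatigue_drift_per_trial = 0, rebound_amplitude = 0)
  t <- seq(0, 1, by = 0.05)
  log <- simulate_sensor_log(rep(0.01, length(t)), t, phys, 0,
                             as.POSIXct("2024-01-01", tz = "UTC"), 1, "trial")
  # dR/R = K * eps: every sample encodes 1010 ohms = 10100 counts
  expect_true(all(log$counts == 10100))
  expect_true(all(log$hex == toupper(as.hexmode(10100L))))
})

test_that("saturation clips the encoded resistance at the configured strain", {
  phys <- sensor_physics(baseline_resistance_ohm = 1000, gauge_factor = 1,
                         noise_sd = 0, spike_rate = 0, saturation_strain = 0.05,
                         fatigue_drift_per_trial = 0, rebound_amplitude = 0)
  t <- seq(0, 1, length.out = 101)
  eps <- seq(0, 0.10, length.out = 101)   # ramp past saturation
  r <- simulate_resistance(eps, t, phys, 0)
  expect_equal(max(r), 1000 * 1.05)
  expect_true(all(r[eps >= 0.05] == 1000 * 1.05))
})

test_that("fatigue drift scales the baseline with trial index", {
  phys <- sensor_physics(baseline_resistance_ohm = 1000, gauge_factor = 2,
                         noise_sd = 0, spike_rate = 0, saturation_strain = Inf,
                         fatigue_drift_per_trial = 0.01, rebound_amplitude = 0)
  t <- 0:4
  r0 <- simulate_resistance(rep(0, 5), t, phys, 0)
  r3 <- simulate_resistance(rep(0, 5), t, phys, 3)
  expect_equal(unique(r0), 1000)
  expect_equal(unique(r3), 1030)
})

test_that("compression release triggers a decaying rebound transient", {
  phys <- sensor_physics(baseline_resistance_ohm = 1000, gauge_factor = 1,
                         noise_sd = 0, spike_rate = 0, saturation_strain = Inf,
                         fatigue_drift_per_trial = 0,
                         rebound_amplitude = 0.03, rebound_tau_s = 0.5,
                         rebound_trigger = 0.01)
  t <- seq(0, 4, by = 0.01)
  eps <- ifelse(t >= 1 & t <= 2, -0.05, 0)  # compression pulse then release
  r <- simulate_resistance(eps, t, phys, 0)
  # oracle: direct evaluation of the stated formula
  release <- which(eps[-length(eps)] < -0.01 & eps[-1] >= -0.01) + 1
  expect_length(release, 1)
  eff <- pmin(pmax(eps, -Inf), Inf)
  idx <- seq(release, length(t))
  eff[idx] <- eff[idx] + 0.03 * exp(-(t[idx] - t[release]) / 0.5)
  expect_equal(r, 1000 * (1 + eff), tolerance = 1e-12)
  # post-release resistance transiently exceeds baseline before decaying back
  post <- r[t > t[release]]
  expect_gt(max(post), 1000)
  expect_lt(post[length(post)], 1000 * 1.001)
})

test_that("negative simulated resistance signals inconsistent physics", {
  phys <- sensor_physics(baseline_resistance_ohm = 100, gauge_factor = 10,
                         noise_sd = 0, spike_rate = 0, saturation_strain = Inf,
                         fatigue_drift_per_trial = 0, rebound_amplitude = 0)
  expect_error(simulate_resistance(c(0, -0.2), c(0, 1), phys, 0), "negative")
})

test_that("generated scenarios are complete and byte-identical under a fixed seed", {
  cfg <- tiny_scenario(n_participants = 1, seed = 5)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  man1 <- generate_scenario(cfg, d1)
  generate_scenario(cfg, d2)
  # 6 movements -> 6 trials x 6 sensors = 36 sensor logs + 6 marker files
  expect_length(man1$trials, 6)
  logs <- list.files(d1, pattern = "sensor[0-9]\\.csv$")
  expect_length(logs, 36)
  expect_length(list.files(d1, pattern = "markers\\.tsv$"), 6)
  for (f in sort(list.files(d1))) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
})

test_that("changing the seed changes noise realizations but not angle peaks", {
  phys <- sensor_physics(noise_sd = 3)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  generate_scenario(tiny_scenario(1, physics = phys, seed = 1,
                                  movements = "forward_flexion"), d1)
  generate_scenario(tiny_scenario(1, physics = phys, seed = 2,
                                  movements = "forward_flexion"), d2)
  r1 <- decode_log(file.path(d1, "P01_forward_flexion_sensor1.csv"))
  r2 <- decode_log(file.path(d2, "P01_forward_flexion_sensor1.csv"))
  expect_false(identical(r1$r, r2$r))
  s1 <- read_marker_tsv(file.path(d1, "P01_forward_flexion_markers.tsv"))
  s2 <- read_marker_tsv(file.path(d2, "P01_forward_flexion_markers.tsv"))
  a1 <- compute_lumbar_angles(s1); a2 <- compute_lumbar_angles(s2)
  expect_equal(min(a1$upper_x), min(a2$upper_x), tolerance = 1e-9)
})

test_that("noiseless pipeline recovers the configured strain pointwise (beyond quantization)", {
  phys <- ideal_sensor_physics(baseline_resistance_ohm = 2000, gauge_factor = 5)
  t <- seq(0, 3, by = 0.02)
  f <- angle_profile_fun(tiny_entry(reps = 1, fractions = 1), 1.5)
  eps_true <- 0.12 * f(t) / 30
  log <- simulate_sensor_log(eps_true, t, phys, 0,
                             as.POSIXct("2024-01-01", tz = "UTC"), 1, "x")
  path <- withr::local_tempfile(fileext = ".csv")
  write_sensor_log(log, path)
  rs <- decode_log(path)
  st <- compute_strain(rs, gauge_factor = 5)
  # oracle: exact forward formula including quantization
  r_expected <- round(2000 * (1 + 5 * eps_true) / 0.1) * 0.1
  eps_expected <- (r_expected - 2000) / (5 * 2000)
  expect_equal(st$eps, eps_expected, tolerance = 1e-9)
  expect_equal(st$baseline_r0, 2000)
})
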