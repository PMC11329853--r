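test_that("marker TSV write/read round trip preserves positions and gaps", {
  prof <- generate_angle_profile(tiny_entry(), 60, 1.5)
  seq <- synthesize_marker_trajectories(prof, "forward_flexion")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_marker_tsv(seq, path)
  back <- read_marker_tsv(path)
  expect_setequal(marker_labels(back), marker_labels(seq))
  for (lab in marker_labels(seq))
    expect_equal(back$positions[, , lab], seq$positions[, , lab],
                 tolerance = 1e-4, ignore_attr = TRUE)

  # blank a frame of one marker -> flagged missing, others intact
  seq2 <- seq
  seq2$positions[3, , "L3"] <- NA
  write_marker_tsv(seq2, path)
  back2 <- read_marker_tsv(path)
  expect_true(all(is.na(back2$positions[3, , "L3"])))
  expect_false(anyNA(back2$positions[-3, , "L3"]))

  expect_error(read_marker_tsv(path, required_labels = "STERNUM"), "STERNUM")
  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines("Frame\tTime\tA_X\tA_Y\tA_Z", empty)
  expect_error(read_marker_tsv(empty), "empty")
})

test_that("gap interpolation is exact on linear data and accurate on sinusoids", {
  t <- seq(0, 2, by = 1 / 179)
  n <- length(t)
  lin <- cbind(3 * t + 1, -2 * t, t)
  sine <- cbind(10 * sin(2 * pi * t), 5 * cos(2 * pi * t), t)
  pos <- array(NA_real_, c(n, 3, 2), dimnames = list(NULL, NULL, c("A", "B")))
  pos[, , "A"] <- lin
  pos[, , "B"] <- sine
  seq <- marker_seq(t, pos)

  # no gaps -> identity
  same <- interpolate_gaps(seq)
  expect_equal(same$positions, seq$positions)

  gappy <- seq
  gappy$positions[100, , "A"] <- NA          # 1-frame gap, linear
  gappy$positions[200:202, , "B"] <- NA      # 3-frame gap, sinusoid
  filled <- interpolate_gaps(gappy, max_gap_frames = 5)
  expect_equal(filled$positions[100, , "A"], lin[100, ], tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_lt(max(abs(filled$positions[200:202, , "B"] - sine[200:202, ])), 0.1)

  # gaps beyond the limit are refused, naming marker and span
  gappy$positions[50:70, , "A"] <- NA
  expect_error(interpolate_gaps(gappy, max_gap_frames = 5), "marker A")
})

test_that("segment frames recover rigid rotations exactly", {
  geom <- default_marker_geometry()
  # neutral pose -> identity by construction
  f0 <- build_segment_frame(geom["L1_left", ], geom["L1_right", ], geom["L3", ])
  expect_equal(f0$rotation, diag(3), tolerance = 1e-12)
  expect_equal(f0$origin, (geom["L1_left", ] + geom["L1_right", ]) / 2)

  set.seed(10)
  for (i in 1:50) {
    Q <- random_rotation()
    f <- build_segment_frame(as.vector(Q %*% geom["L1_left", ]),
                             as.vector(Q %*% geom["L1_right", ]),
                             as.vector(Q %*% geom["L3", ]))
    expect_lt(max(abs(f$rotation - Q)), 1e-9)
    # orthonormal, right-handed
    expect_lt(max(abs(crossprod(f$rotation) - diag(3))), 1e-9)
    expect_equal(det(f$rotation), 1, tolerance = 1e-9)
  }
})

test_that("degenerate marker configurations raise geometry errors", {
  expect_error(build_segment_frame(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)),
               "collinear")
  expect_error(build_segment_frame(c(0, 0, 0), c(0, 0, 0), c(1, 1, 1)),
               "coincide")
  # a left/right swap cannot break handedness (PA = ML x SI keeps det = +1);
  # it shows up as a 180-degree rotation about the SI axis instead
  geom <- default_marker_geometry()
  f <- build_segment_frame(geom["L1_right", ], geom["L1_left", ], geom["L3", ])
  expect_equal(det(f$rotation), 1, tolerance = 1e-12)
  expect_equal(f$rotation, diag(c(-1, 1, -1)), tolerance = 1e-12)
})

test_that("Euler XYZ decomposition inverts composition on the canonical branch", {
  expect_equal(euler_xyz(diag(3)), c(x = 0, y = 0, z = 0))
  expect_equal(euler_xyz(compose_euler_xyz(c(30, 0, 0))),
               c(x = 30, y = 0, z = 0), tolerance = 1e-12)
  expect_equal(euler_xyz(compose_euler_xyz(c(0, -40, 25))),
               c(x = 0, y = -40, z = 25), tolerance = 1e-12)
  set.seed(11)
  for (i in 1:500) {
    R <- random_rotation()
    expect_lt(max(abs(compose_euler_xyz(euler_xyz(R)) - R)), 1e-9)
  }
  expect_error(euler_xyz(matrix(1:9 / 10, 3, 3)), "not a rotation")
  expect_warning(euler_xyz(compose_euler_xyz(c(10, 89.9, -5))), "gimbal")
})

test_that("lumbar angles trace the configured profile per movement and plane", {
  for (m in c("forward_flexion", "left_lateral_bend", "right_rotation")) {
    entry <- tiny_entry(m, reps = 1, fractions = 1, end_range = 24)
    prof <- generate_angle_profile(entry, 60, 1.5)
    seq <- synthesize_marker_trajectories(prof, m,
                                          shares = c(lower = 0.4, upper = 0.6))
    ang <- compute_lumbar_angles(seq)
    ax <- movement_axis(m)
    up <- ang[[paste0("upper_", ax$component)]]
    lo <- ang[[paste0("lower_", ax$component)]]
    expect_lt(max(abs(up - ax$sign * 0.6 * prof$angle_deg)), 1e-6)
    expect_lt(max(abs(lo - ax$sign * 0.4 * prof$angle_deg)), 1e-6)
    others <- setdiff(c("x", "y", "z"), ax$component)
    for (o in others) {
      expect_lt(max(abs(ang[[paste0("upper_", o)]])), 1e-6)
      expect_lt(max(abs(ang[[paste0("lower_", o)]])), 1e-6)
    }
  }
})

test_that("angles are invariant to a rigid rotation of the whole lab frame", {
  prof <- generate_angle_profile(tiny_entry(end_range = 20), 60, 1.5)
  seq <- synthesize_marker_trajectories(prof, "left_lateral_bend")
  set.seed(12)
  Q <- random_rotation()
  rotated <- seq
  for (lab in marker_labels(seq))
    rotated$positions[, , lab] <- seq$positions[, , lab] %*% t(Q)
  a1 <- compute_lumbar_angles(seq)
  a2 <- compute_lumbar_angles(rotated)
  expect_equal(a2, a1, tolerance = 1e-9)
})

test_that("low-pass filtering attenuates marker jitter without biasing the movement", {
  set.seed(13)
  prof <- generate_angle_profile(tiny_entry(reps = 1, fractions = 1,
                                            end_range = 30), 179, 3)
  noisy <- synthesize_marker_trajectories(prof, "forward_flexion",
                                          marker_noise_mm = 0.5)
  raw <- compute_lumbar_angles(noisy)
  smooth <- compute_lumbar_angles(noisy, lowpass_hz = 6)
  truth <- -0.5 * prof$angle_deg
  rmse <- function(x) sqrt(mean((x - truth)^2))
  expect_lt(rmse(smooth$upper_x), rmse(raw$upper_x))
  expect_lt(rmse(smooth$upper_x), 0.3)
})
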