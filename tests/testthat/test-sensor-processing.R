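make_log_file <- function(hex, start = "2024-01-01T00:00:00.000Z",
                          dt = 0.04, sensor_id = 1, trial_id = "T") {
  start_t <- as.POSIXct(sub("Z$", "", start), format = "%Y-%m-%dT%H:%M:%OS",
                        tz = "UTC")
  stamps <- format(start_t + (seq_along(hex) - 1) * dt,
                   "%Y-%m-%dT%H:%M:%OS3Z", tz = "UTC")
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  writeLines(c(paste0("sensor_id,", sensor_id),
               paste0("trial_id,", trial_id),
               paste0("start,", start),
               paste(stamps, hex, sep = ",")), path)
  path
}

test_that("hex fields decode to counts and ohms at 0.1 ohm per count", {
  path <- make_log_file(c("3E8", "FF", "0", "88B8"))
  rs <- decode_log(path)
  expect_equal(rs$counts, c(1000, 255, 0, 35000))
  expect_equal(rs$r, c(100.0, 25.5, 0, 3500.0))
  expect_equal(rs$sensor_id, 1L)
})

test_that("the time vector is generated linearly from start to last timestamp", {
  path <- make_log_file(rep("64", 11), dt = 0.1)
  rs <- decode_log(path)
  expect_equal(rs$t, seq(0, 1, by = 0.1), tolerance = 1e-9)
})

test_that("malformed hex and non-monotone timestamps are rejected with the offending line", {
  path <- make_log_file(c("3E8", "XYZ", "FF"))
  expect_error(decode_log(path), "line 5")
  lines <- readLines(make_log_file(c("1", "2", "3")))
  lines <- lines[c(1, 2, 3, 6, 5, 4)]   # scramble the data rows
  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(lines, path2)
  expect_error(decode_log(path2), "monotone")
})

test_that("encode/decode round trip is lossless at the count level", {
  set.seed(3)
  counts <- sample.int(5e4, 500)
  t <- seq(0, 10, length.out = 500)
  log <- structure(list(sensor_id = 2L, trial_id = "rt",
                        start_time = as.POSIXct("2024-01-01", tz = "UTC"),
                        t = t, counts = counts, hex = encode_hex(counts)),
                   class = "sensor_log")
  path <- withr::local_tempfile(fileext = ".csv")
  write_sensor_log(log, path)
  expect_identical(decode_log(path)$counts, as.integer(counts))
})

test_that("strain derivation matches the gauge-factor relation", {
  rs <- structure(list(sensor_id = 1L, trial_id = "s",
                       start_time = as.POSIXct("2024-01-01", tz = "UTC"),
                       t = c(0, 1, 2), r = c(1000, 1000, 1010)),
                  class = "resistance_series")
  s1 <- compute_strain(rs, baseline_mode = "first_sample")
  expect_equal(s1$eps, c(0, 0, 0.01))
  expect_true(is.na(s1$gauge_factor_used))
  s2 <- compute_strain(rs, baseline_mode = "first_sample", gauge_factor = 2)
  expect_equal(s2$eps, c(0, 0, 0.005))
  rs$r <- rep(1234, 3)
  expect_equal(compute_strain(rs)$eps, c(0, 0, 0))
})

test_that("Hampel filter replaces isolated spikes and leaves smooth signals alone", {
  x <- rep(5, 31)
  x[16] <- 105
  f <- hampel_filter(x, 5, 3)
  expect_equal(f$x, rep(5, 31))
  expect_equal(sum(f$outliers), 1)
  expect_true(f$outliers[16])

  ramp <- seq(0, 1, length.out = 100)
  f2 <- hampel_filter(ramp, 5, 3)
  expect_equal(f2$x, ramp)
  expect_false(any(f2$outliers))
})

test_that("Hampel filter equals the brute-force oracle on random series", {
  set.seed(42)
  for (k in c(3, 5, 9)) {
    x <- cumsum(rnorm(1000))
    x[sample(1000, 10)] <- x[sample(1000, 10)] + 50
    got <- hampel_filter(x, k, 3)
    want <- brute_hampel(x, k, 3)
    expect_identical(got$x, want$x)
    expect_identical(got$outliers, want$outliers)
  }
})

test_that("Hampel filter agrees with pracma's on interior samples", {
  skip_if_not_installed("pracma")
  set.seed(1)
  x <- sin(seq(0, 10, length.out = 300)) + rnorm(300, sd = 0.05)
  x[c(50, 151, 260)] <- x[c(50, 151, 260)] + 3
  k <- 7
  got <- hampel_filter(x, k, 3)
  ref <- pracma::hampel(x, k, t0 = 3)
  interior <- (k + 1):(300 - k)
  expect_equal(got$x[interior], ref$y[interior])
})

test_that("Hampel filter is idempotent on its designed use case", {
  # smooth signal + measurement noise + isolated spikes: once the spikes are
  # replaced, a second pass changes nothing
  set.seed(9)
  t <- seq(0, 10, length.out = 500)
  x <- 100 * sin(t) + rnorm(500, sd = 0.5)
  x[c(40, 200, 433)] <- x[c(40, 200, 433)] + 50
  once <- hampel_filter(x, 5, 3)
  expect_equal(sort(which(once$outliers)), c(40L, 200L, 433L))
  twice <- hampel_filter(once$x, 5, 3)
  expect_equal(twice$x, once$x)
  expect_false(any(twice$outliers))
})

test_that("Hampel filter validates its parameters", {
  expect_error(hampel_filter(1:100, 0, 3), "window_halfwidth")
  expect_error(hampel_filter(1:100, 5, 0), "n_mad")
  expect_error(hampel_filter(1:5, 5, 3), "longer than series")
})

qc_frame <- function(stat, movement = "forward_flexion", sensor = 1) {
  data.frame(participant_id = sprintf("P%02d", seq_along(stat)),
             movement = movement, sensor_id = sensor, statistic = stat)
}

test_that("identical streams are never flagged (zero SD handled)", {
  qc <- flag_failed_streams(qc_frame(rep(1000, 10)))
  expect_false(any(qc$flagged))
})

test_that("a planted failure at 11 population SDs is the only stream flagged", {
  set.seed(2)
  base <- 1000 + rnorm(9)
  outlier <- mean(base) + 11 * sd(base)
  qc <- flag_failed_streams(qc_frame(c(base, outlier)), threshold_sd = 10)
  expect_equal(which(qc$flagged), 10L)
  expect_equal(attr(qc, "n_flagged"), 1L)
  # the recorded population stats satisfy the flag relation exactly
  i <- 10
  expect_true(abs(qc$statistic[i] - qc$population_mean[i]) >
              qc$threshold_sd[i] * qc$population_sd[i])
})

test_that("QC counts planted failures exactly and reports the removal fraction", {
  set.seed(4)
  frames <- list()
  for (s in 1:6) {
    stat <- 1000 + rnorm(6)
    frames[[s]] <- qc_frame(stat, sensor = s)
  }
  df <- do.call(rbind, frames)
  # plant 2 failures in 36 streams
  df$statistic[c(3, 20)] <- df$statistic[c(3, 20)] + 5000
  qc <- flag_failed_streams(df, threshold_sd = 10)
  expect_equal(attr(qc, "n_flagged"), 2L)
  expect_equal(attr(qc, "removal_fraction"), 2 / 36)
  expect_equal(sort(which(qc$flagged)), c(3L, 20L))
})

test_that("QC flagging is invariant to participant ordering and monotone in the threshold", {
  set.seed(6)
  df <- qc_frame(c(1000 + rnorm(8, sd = 2), 1200))
  qc1 <- flag_failed_streams(df, threshold_sd = 10)
  perm <- sample(nrow(df))
  qc2 <- flag_failed_streams(df[perm, ], threshold_sd = 10)
  expect_equal(qc2$flagged, qc1$flagged[perm])
  # stricter thresholds can only flag more
  for (th in c(1, 3, 5, 10, 50)) {
    lo <- flag_failed_streams(df, threshold_sd = th)$flagged
    hi <- flag_failed_streams(df, threshold_sd = th * 2)$flagged
    expect_true(all(lo | !hi))
  }
})

test_that("single-stream groups warn and flag nothing", {
  expect_warning(qc <- flag_failed_streams(qc_frame(1000)), "single stream")
  expect_false(any(qc$flagged))
})
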