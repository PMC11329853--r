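# Independent brute-force oracles and small fixture builders shared by tests.

# Direct-sum zero-lag cross-correlation coefficient.
brute_xcorr0 <- function(x, y) {
  num <- 0
  ex <- 0
  ey <- 0
  for (i in seq_along(x)) {
    num <- num + x[i] * y[i]
    ex <- ex + x[i]^2
    ey <- ey + y[i]^2
  }
  num / sqrt(ex * ey)
}

# Brute-force sliding-window Hampel filter with truncated edge windows,
# written directly from the definition.
brute_hampel <- function(x, k, n_mad) {
  n <- length(x)
  out <- x
  mask <- logical(n)
  for (i in seq_len(n)) {
    w <- x[max(1, i - k):min(n, i + k)]
    med <- median(w)
    sig <- 1.4826 * median(abs(w - med))
    if (abs(x[i] - med) > n_mad * sig) {
      out[i] <- med
      mask[i] <- TRUE
    }
  }
  list(x = out, outliers = mask)
}

# Uniform random rotation matrix via a normalized quaternion.
random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

# Small, fast scenario for pipeline-level tests.
tiny_scenario <- function(n_participants = 2, physics = ideal_sensor_physics(),
                          seed = 11, movements = NULL, ...) {
  protocol <- default_protocol()
  if (!is.null(movements))
    protocol <- Filter(function(e) e$movement %in% movements, protocol)
  scenario_config(n_participants = n_participants, protocol = protocol,
                  physics = physics, mocap_rate_hz = 60, sensor_rate_hz = 25,
                  rep_duration_s = 1.5, seed = seed, ...)
}

# One short protocol entry for unit tests.
tiny_entry <- function(movement = "forward_flexion", reps = 2,
                       fractions = c(0.5, 1), end_range = 30) {
  position <- if (grepl("rotation", movement)) "seated" else "standing"
  protocol_entry(movement, position, reps, fractions, end_range)
}
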