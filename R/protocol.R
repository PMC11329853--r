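#' Movement vocabulary
#'
#' The six low back movements in the validation protocol, in canonical order.
#'
#' @return Character vector of movement names.
#' @export
movement_levels <- function() {
  c("forward_flexion", "extension",
    "left_lateral_bend", "right_lateral_bend",
    "left_rotation", "right_rotation")
}

#' Default set of movements whose normalized kinematic angle is sign-flipped
#'
#' Forward flexion, left lateral bending, and right (seated) rotation produce
#' convention-negative primary-plane angles under the package's segment axis
#' conventions; multiplying their normalized angle by -1 makes the primary
#' movement direction positive for every movement, as required before
#' cross-correlation.
#'
#' @return Character vector of movement names.
#' @export
default_flip_set <- function() {
  c("forward_flexion", "left_lateral_bend", "right_rotation")
}

#' Construct one movement-protocol entry
#'
#' One entry describes how a single movement is performed in the protocol:
#' how many repetitions, to what fraction of end range each, and what the
#' end-range amplitude is (total lumbar excursion, degrees).
#'
#' @param movement One of [movement_levels()].
#' @param position `"standing"` or `"seated"`.
#' @param repetitions Number of repetitions (>= 1).
#' @param amplitude_fractions Fraction of end range reached on each repetition,
#'   each in (0, 1]; length must equal `repetitions`.
#' @param end_range_deg End-range amplitude in degrees (> 0).
#' @return A list of class `"protocol_entry"`.
#' @export
protocol_entry <- function(movement, position, repetitions,
                           amplitude_fractions, end_range_deg) {
  movement <- match.arg(movement, movement_levels())
  position <- match.arg(position, c("standing", "seated"))
  if (!is.numeric(repetitions) || length(repetitions) != 1L || repetitions < 1)
    stop("repetitions must be a single count >= 1")
  repetitions <- as.integer(repetitions)
  if (length(amplitude_fractions) != repetitions)
    stop("length(amplitude_fractions) must equal repetitions")
  if (any(amplitude_fractions <= 0 | amplitude_fractions > 1))
    stop("every amplitude fraction must lie in (0, 1]")
  if (!is.numeric(end_range_deg) || end_range_deg <= 0)
    stop("end_range_deg must be positive")
  structure(
    list(movement = movement, position = position,
         repetitions = repetitions,
         amplitude_fractions = as.numeric(amplitude_fractions),
         end_range_deg = as.numeric(end_range_deg)),
    class = "protocol_entry"
  )
}

#' Default movement protocol
#'
#' The study protocol: three repetitions to end range on each side for lateral
#' bending (standing) and rotation (seated); three repetitions to approximately
#' 50% of end range for extension; and two repetitions to approximately 50% of
#' end range plus one to 100% for forward flexion. The sub-maximal flexion and
#' extension repetitions protect the sensing element from reaching its
#' resistance limits early in a session.
#'
#' End-range amplitudes are not part of the protocol description and default to
#' typical healthy-adult lumbar ranges: 50 deg flexion, 30 deg extension,
#' 25 deg lateral bend, 30 deg axial rotation (total lumbar excursion).
#'
#' @param end_ranges_deg Named numeric vector of end-range amplitudes with
#'   names `flexion`, `extension`, `lateral`, `rotation`.
#' @return List of [protocol_entry()] objects, one per movement.
#' @export
default_protocol <- function(end_ranges_deg = c(flexion = 50, extension = 30,
                                                lateral = 25, rotation = 30)) {
  list(
    protocol_entry("forward_flexion", "standing", 3, c(0.5, 0.5, 1.0),
                   end_ranges_deg[["flexion"]]),
    protocol_entry("extension", "standing", 3, c(0.5, 0.5, 0.5),
                   end_ranges_deg[["extension"]]),
    protocol_entry("left_lateral_bend", "standing", 3, c(1, 1, 1),
                   end_ranges_deg[["lateral"]]),
    protocol_entry("right_lateral_bend", "standing", 3, c(1, 1, 1),
                   end_ranges_deg[["lateral"]]),
    protocol_entry("left_rotation", "seated", 3, c(1, 1, 1),
                   end_ranges_deg[["rotation"]]),
    protocol_entry("right_rotation", "seated", 3, c(1, 1, 1),
                   end_ranges_deg[["rotation"]])
  )
}

#' Anatomical rotation axis and sign for a movement
#'
#' Maps each movement to the Euler component of the XYZ sequence that carries
#' it (X about the mediolateral axis for flexion/extension, Y about the
#' superoinferior axis for axial rotation, Z about the posteroanterior axis
#' for lateral bending) and to the sign of that component under the package's
#' right-handed segment frames (X = left-to-right, Y = up, Z = posterior-to-
#' anterior). Forward flexion, left lateral bend, and right rotation are the
#' convention-negative directions (hence [default_flip_set()]).
#'
#' @param movement One of [movement_levels()].
#' @return List with `component` (`"x"`, `"y"`, or `"z"`), `axis` (unit
#'   3-vector in the lab frame), and `sign` (+1 or -1).
#' @export
movement_axis <- function(movement) {
  movement <- match.arg(movement, movement_levels())
  switch(movement,
    forward_flexion    = list(component = "x", axis = c(1, 0, 0), sign = -1),
    extension          = list(component = "x", axis = c(1, 0, 0), sign = +1),
    left_lateral_bend  = list(component = "z", axis = c(0, 0, 1), sign = -1),
    right_lateral_bend = list(component = "z", axis = c(0, 0, 1), sign = +1),
    left_rotation      = list(component = "y", axis = c(0, 1, 0), sign = +1),
    right_rotation     = list(component = "y", axis = c(0, 1, 0), sign = -1)
  )
}

#' Continuous reference angle profile for a protocol entry
#'
#' Builds the unsigned angle-versus-time function for one movement trial: one
#' raised-cosine excursion per repetition (peak = amplitude fraction x end
#' range), separated by rest, with lead-in and tail rest so the trial starts
#' and ends in the neutral position. The raised cosine is C1: angle and
#' angular velocity are zero at every repetition boundary.
#'
#' @param entry A [protocol_entry()].
#' @param rep_duration_s Duration of one repetition, seconds (> 0).
#' @param rest_s Rest between repetitions, seconds.
#' @param lead_s Lead-in rest before the first repetition, seconds.
#' @param tail_s Tail rest after the last repetition, seconds.
#' @return A function of time (seconds) returning the unsigned angle in
#'   degrees, with attribute `"duration_s"` giving the total trial duration.
#' @export
angle_profile_fun <- function(entry, rep_duration_s = 3,
                              rest_s = 1, lead_s = 1, tail_s = 1) {
  stopifnot(inherits(entry, "protocol_entry"))
  if (rep_duration_s <= 0) stop("rep_duration_s must be positive")
  if (rest_s < 0 || lead_s < 0 || tail_s < 0)
    stop("rest/lead/tail durations must be non-negative")
  peaks <- entry$amplitude_fractions * entry$end_range_deg
  starts <- lead_s + (seq_along(peaks) - 1) * (rep_duration_s + rest_s)
  duration <- lead_s + length(peaks) * rep_duration_s +
    (length(peaks) - 1) * rest_s + tail_s
  f <- function(t) {
    ang <- numeric(length(t))
    for (k in seq_along(peaks)) {
      tau <- t - starts[k]
      inside <- tau >= 0 & tau <= rep_duration_s
      ang[inside] <- peaks[k] * 0.5 * (1 - cos(2 * pi * tau[inside] / rep_duration_s))
    }
    ang
  }
  attr(f, "duration_s") <- duration
  f
}

#' Sample a reference angle profile at a fixed rate
#'
#' @inheritParams angle_profile_fun
#' @param rate_hz Sampling rate, Hz (> 0).
#' @return Data frame with columns `t` (seconds) and `angle_deg` (unsigned).
#' @export
generate_angle_profile <- function(entry, rate_hz, rep_duration_s = 3,
                                   rest_s = 1, lead_s = 1, tail_s = 1) {
  if (!is.numeric(rate_hz) || rate_hz <= 0) stop("rate_hz must be positive")
  f <- angle_profile_fun(entry, rep_duration_s, rest_s, lead_s, tail_s)
  duration <- attr(f, "duration_s")
  t <- seq(0, duration, by = 1 / rate_hz)
  data.frame(t = t, angle_deg = f(t))
}
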