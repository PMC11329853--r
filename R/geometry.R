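#' Nominal marker geometry for the multisegmental lumbar spine model
#'
#' Neutral-standing positions (millimeters) of the 18 reflective markers:
#' spinous processes T12-L5, bilateral markers ~4 cm lateral to L1 and L4, and
#' bilateral posterior superior iliac spine (PSIS), anterior superior iliac
#' spine (ASIS), posterior pelvis, and iliac crest markers. Lab frame:
#' X = left-to-right (mediolateral), Y = inferior-to-superior, Z = posterior-
#' to-anterior; origin near the L5 spinous process. Vertebral spacing defaults
#' to 38 mm, a typical adult lumbar level-to-level distance. The geometry is
#' constructed so that every segment frame is the identity rotation in the
#' neutral pose.
#'
#' @param vertebral_spacing_mm Craniocaudal distance between adjacent spinous
#'   markers, mm.
#' @param lateral_offset_mm Distance of the L1/L4 lateral markers from the
#'   midline, mm (the study placed them approximately 4 cm out).
#' @return Named 18 x 3 matrix of marker positions (mm), rows = marker labels,
#'   columns = X, Y, Z.
#' @export
default_marker_geometry <- function(vertebral_spacing_mm = 38,
                                    lateral_offset_mm = 40) {
  s <- vertebral_spacing_mm
  w <- lateral_offset_mm
  z_back <- -50   # skin surface posterior to the mid-axis
  m <- rbind(
    T12 = c(0, 5 * s, z_back),
    L1  = c(0, 4 * s, z_back),
    L2  = c(0, 3 * s, z_back),
    L3  = c(0, 2 * s, z_back),
    L4  = c(0, 1 * s, z_back),
    L5  = c(0, 0 * s, z_back),
    L1_left  = c(-w, 4 * s, z_back),
    L1_right = c(+w, 4 * s, z_back),
    L4_left  = c(-w, 1 * s, z_back),
    L4_right = c(+w, 1 * s, z_back),
    PSIS_left  = c(-40, -40, -60),
    PSIS_right = c(+40, -40, -60),
    # crest pair directly superior to the PSIS pair (same Z) so the pelvis
    # superoinferior axis is vertical in the neutral pose
    crest_left  = c(-120, -10, -60),
    crest_right = c(+120, -10, -60),
    ASIS_left  = c(-110, -45, 80),
    ASIS_right = c(+110, -45, 80),
    postpel_left  = c(-20, -65, -70),
    postpel_right = c(+20, -65, -70)
  )
  colnames(m) <- c("X", "Y", "Z")
  m
}

#' Segment definitions of the spine model
#'
#' Marker labels defining each segment frame. The upper lumbar segment is
#' defined by the markers lateral to L1 plus the L3 spinous marker; the lower
#' lumbar segment by the markers lateral to L4 plus the L5 spinous marker; the
#' pelvis by the PSIS pair (origin), the ASIS pair (mediolateral direction),
#' and the iliac crest pair (superoinferior direction). Remaining pelvis
#' markers are redundancy only.
#'
#' @return Named list with elements `upper_lumbar`, `lower_lumbar`, `pelvis`,
#'   each a list of labeled marker roles.
#' @export
spine_model_definition <- function() {
  list(
    upper_lumbar = list(lateral_left = "L1_left", lateral_right = "L1_right",
                        inferior = "L3"),
    lower_lumbar = list(lateral_left = "L4_left", lateral_right = "L4_right",
                        inferior = "L5"),
    pelvis = list(origin_left = "PSIS_left", origin_right = "PSIS_right",
                  ml_left = "ASIS_left", ml_right = "ASIS_right",
                  si_left = "crest_left", si_right = "crest_right")
  )
}

#' Marker labels belonging to each rigid segment (for rigidity checks and the
#' forward model)
#' @return Named list of character vectors.
#' @export
segment_marker_sets <- function() {
  list(
    upper_lumbar = c("T12", "L1", "L2", "L3", "L1_left", "L1_right"),
    lower_lumbar = c("L4", "L5", "L4_left", "L4_right"),
    pelvis = c("PSIS_left", "PSIS_right", "ASIS_left", "ASIS_right",
               "postpel_left", "postpel_right", "crest_left", "crest_right")
  )
}

rotation_about_axis <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  c <- cos(th); s <- sin(th)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  matrix(c(
    c + ux^2 * (1 - c),       ux * uy * (1 - c) - uz * s, ux * uz * (1 - c) + uy * s,
    uy * ux * (1 - c) + uz * s, c + uy^2 * (1 - c),       uy * uz * (1 - c) - ux * s,
    uz * ux * (1 - c) - uy * s, uz * uy * (1 - c) + ux * s, c + uz^2 * (1 - c)
  ), nrow = 3, byrow = TRUE)
}

#' Construct a marker frame sequence object
#'
#' @param t Time vector, seconds.
#' @param positions Numeric array `n_frames x 3 x n_markers` with marker labels
#'   as the third dimnames; units mm. `NA` coordinates mark gaps.
#' @return Object of class `"marker_seq"`.
#' @export
marker_seq <- function(t, positions) {
  stopifnot(is.array(positions), length(dim(positions)) == 3,
            dim(positions)[1] == length(t), dim(positions)[2] == 3)
  if (is.null(dimnames(positions)[[3]]))
    stop("positions must carry marker labels as third dimnames")
  structure(list(t = as.numeric(t), positions = positions),
            class = "marker_seq")
}

#' @export
print.marker_seq <- function(x, ...) {
  cat(sprintf("marker_seq: %d frames, %d markers, %.2f s\n",
              length(x$t), dim(x$positions)[3], diff(range(x$t))))
  invisible(x)
}

#' Marker labels of a marker sequence
#' @param seq A `marker_seq`.
#' @return Character vector.
#' @export
marker_labels <- function(seq) dimnames(seq$positions)[[3]]

#' Synthesize rigid-segment marker trajectories for one movement trial
#'
#' Forward kinematic model inverse to [compute_lumbar_angles()]. The pelvis is
#' fixed; the lower lumbar segment rotates relative to the pelvis by
#' `shares["lower"]` of the signed reference angle about the movement's
#' anatomical axis (pivoting at the lumbosacral junction), and the upper
#' lumbar segment rotates relative to the lower by `shares["upper"]` of the
#' angle (pivoting at the L3-L4 junction). All markers of a segment move
#' rigidly; at zero angle every marker sits at its nominal position.
#'
#' @param angle_series Data frame with columns `t` and `angle_deg` (unsigned
#'   profile, e.g. from [generate_angle_profile()]).
#' @param movement One of [movement_levels()]; fixes the rotation axis and the
#'   sign of the excursion.
#' @param geometry Nominal marker matrix from [default_marker_geometry()].
#' @param shares Named numeric vector `c(lower=, upper=)`; fractions of the
#'   reference angle taken up at each joint.
#' @param marker_noise_mm RMS 3D displacement of additive Gaussian marker
#'   noise, mm (0 = noiseless). Per-axis SD is `marker_noise_mm / sqrt(3)`.
#' @return A [marker_seq()].
#' @export
synthesize_marker_trajectories <- function(angle_series, movement,
                                           geometry = default_marker_geometry(),
                                           shares = c(lower = 0.5, upper = 0.5),
                                           marker_noise_mm = 0) {
  movement <- match.arg(movement, movement_levels())
  sets <- segment_marker_sets()
  need <- unlist(sets, use.names = FALSE)
  missing <- setdiff(need, rownames(geometry))
  if (length(missing) > 0)
    stop("geometry is missing markers: ", paste(missing, collapse = ", "))
  ax <- movement_axis(movement)
  t <- angle_series$t
  theta <- ax$sign * angle_series$angle_deg
  n <- length(t)
  labels <- rownames(geometry)
  pos <- array(NA_real_, dim = c(n, 3, length(labels)),
               dimnames = list(NULL, c("X", "Y", "Z"), labels))

  # joint centers: lumbosacral junction between L5 and the sacrum, L3-L4
  # junction between the two lumbar segments (both midline, at skin depth)
  c_lower <- c(0, (geometry["L5", "Y"] + geometry["PSIS_left", "Y"]) / 2, -55)
  c_upper <- (geometry["L3", ] + geometry["L4", ]) / 2

  P_pelvis <- geometry[sets$pelvis, , drop = FALSE]
  P_lower <- geometry[sets$lower_lumbar, , drop = FALSE]
  P_upper <- geometry[sets$upper_lumbar, , drop = FALSE]

  for (i in seq_len(n)) {
    R_low <- rotation_about_axis(ax$axis, shares[["lower"]] * theta[i])
    R_up_rel <- rotation_about_axis(ax$axis, shares[["upper"]] * theta[i])
    pos[i, , sets$pelvis] <- t(P_pelvis)
    pos[i, , sets$lower_lumbar] <-
      c_lower + R_low %*% (t(P_lower) - c_lower)
    # upper lumbar chains through the lower segment
    q_local <- c_upper + R_up_rel %*% (t(P_upper) - c_upper)
    pos[i, , sets$upper_lumbar] <-
      c_lower + R_low %*% (q_local - c_lower)
  }
  if (marker_noise_mm > 0) {
    pos <- pos + stats::rnorm(length(pos), sd = marker_noise_mm / sqrt(3))
  }
  marker_seq(t, pos)
}
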