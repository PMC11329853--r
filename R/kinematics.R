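#' Interpolate short marker gaps
#'
#' Fills missing marker samples (NA, e.g. dropped frames in a mocap export) by
#' per-coordinate cubic spline interpolation over time. Gaps longer than
#' `max_gap_frames` consecutive frames are refused.
#'
#' @param seq A [marker_seq()].
#' @param max_gap_frames Longest fillable gap, frames.
#' @return A gap-free [marker_seq()].
#' @export
interpolate_gaps <- function(seq, max_gap_frames = 10) {
  stopifnot(inherits(seq, "marker_seq"))
  pos <- seq$positions
  t <- seq$t
  for (lab in marker_labels(seq)) {
    gap <- is.na(pos[, 1, lab])
    if (!any(gap)) next
    runs <- rle(gap)
    if (any(runs$lengths[runs$values] > max_gap_frames)) {
      ends <- cumsum(runs$lengths)
      starts <- ends - runs$lengths + 1
      bad <- which(runs$values & runs$lengths > max_gap_frames)[1]
      stop(sprintf("gap of %d frames (frames %d-%d) in marker %s exceeds max_gap_frames=%d",
                   runs$lengths[bad], starts[bad], ends[bad], lab, max_gap_frames))
    }
    if (gap[1] || gap[length(gap)])
      stop("cannot extrapolate a gap at the start/end of marker ", lab)
    for (j in 1:3) {
      ok <- !gap
      pos[gap, j, lab] <- stats::spline(t[ok], pos[ok, j, lab],
                                        xout = t[gap], method = "fmm")$y
    }
  }
  marker_seq(t, pos)
}

#' Low-pass filter marker trajectories
#'
#' 4th-order Butterworth applied forward and backward (zero phase) to every
#' marker coordinate. Requires a uniform, gap-free sequence.
#'
#' @param seq A gap-free [marker_seq()].
#' @param cutoff_hz Cutoff frequency, Hz; must be below the Nyquist rate.
#' @return Filtered [marker_seq()].
#' @export
lowpass_markers <- function(seq, cutoff_hz) {
  stopifnot(inherits(seq, "marker_seq"))
  rate <- 1 / stats::median(diff(seq$t))
  if (cutoff_hz <= 0 || cutoff_hz >= rate / 2)
    stop("cutoff_hz must lie in (0, rate/2)")
  bf <- signal::butter(4, cutoff_hz / (rate / 2), type = "low")
  pos <- seq$positions
  if (anyNA(pos)) stop("fill gaps before low-pass filtering")
  for (m in seq_len(dim(pos)[3])) {
    for (j in 1:3) pos[, j, m] <- signal::filtfilt(bf, pos[, j, m])
  }
  marker_seq(seq$t, pos)
}

#' Build a segment coordinate frame from three markers
#'
#' Anatomical frame construction used for the upper and lower lumbar segments:
#' origin at the midpoint of the lateral marker pair; mediolateral (ML) axis
#' from left to right marker; superoinferior (SI) axis as the component of
#' (origin - inferior midline marker) orthogonal to ML; posteroanterior (PA)
#' axis as ML x SI. The result is right-handed and orthonormal by
#' construction; collinear or coincident markers raise a geometry error. A
#' left/right label swap cannot be detected intrinsically (it yields a proper
#' 180-degree rotation about SI); it surfaces downstream as sign-flipped
#' X and Z angles.
#'
#' @param left,right,inferior Numeric 3-vectors, marker positions (mm).
#' @return List of class `"segment_frame"`: `origin` (mm) and `rotation`
#'   (3 x 3 orthonormal matrix with columns = ML, SI, PA axes in lab
#'   coordinates).
#' @export
build_segment_frame <- function(left, right, inferior) {
  origin <- (left + right) / 2
  ml <- right - left
  nml <- sqrt(sum(ml^2))
  if (nml < 1e-9) stop("lateral markers coincide; cannot build frame")
  ml <- ml / nml
  v <- origin - inferior
  si <- v - sum(v * ml) * ml
  nsi <- sqrt(sum(si^2))
  if (nsi < 1e-9) stop("markers are collinear; cannot build frame")
  si <- si / nsi
  pa <- c(ml[2] * si[3] - ml[3] * si[2],
          ml[3] * si[1] - ml[1] * si[3],
          ml[1] * si[2] - ml[2] * si[1])
  R <- cbind(ml, si, pa)
  dimnames(R) <- NULL
  if (det(R) < 0.5) stop("segment frame is not right-handed; check marker sides")
  structure(list(origin = origin, rotation = R), class = "segment_frame")
}

# Vectorized frame construction over frames: inputs are n x 3 matrices.
# Returns list of nine component vectors rij (rotation columns ML, SI, PA)
# plus origin matrix.
frames_from_markers <- function(left, right, inferior) {
  origin <- (left + right) / 2
  ml <- right - left
  nml <- sqrt(rowSums(ml^2))
  if (any(nml < 1e-9)) stop("lateral markers coincide in some frame")
  ml <- ml / nml
  v <- origin - inferior
  dot <- rowSums(v * ml)
  si <- v - dot * ml
  nsi <- sqrt(rowSums(si^2))
  if (any(nsi < 1e-9)) stop("collinear markers in some frame")
  si <- si / nsi
  pa <- cbind(ml[, 2] * si[, 3] - ml[, 3] * si[, 2],
              ml[, 3] * si[, 1] - ml[, 1] * si[, 3],
              ml[, 1] * si[, 2] - ml[, 2] * si[, 1])
  list(origin = origin,
       r11 = ml[, 1], r21 = ml[, 2], r31 = ml[, 3],
       r12 = si[, 1], r22 = si[, 2], r32 = si[, 3],
       r13 = pa[, 1], r23 = pa[, 2], r33 = pa[, 3])
}

# Relative rotation A^T B per frame, both given as component lists.
relative_rotation_components <- function(A, B) {
  list(
    r11 = A$r11 * B$r11 + A$r21 * B$r21 + A$r31 * B$r31,
    r12 = A$r11 * B$r12 + A$r21 * B$r22 + A$r31 * B$r32,
    r13 = A$r11 * B$r13 + A$r21 * B$r23 + A$r31 * B$r33,
    r21 = A$r12 * B$r11 + A$r22 * B$r21 + A$r32 * B$r31,
    r22 = A$r12 * B$r12 + A$r22 * B$r22 + A$r32 * B$r32,
    r23 = A$r12 * B$r13 + A$r22 * B$r23 + A$r32 * B$r33,
    r31 = A$r13 * B$r11 + A$r23 * B$r21 + A$r33 * B$r31,
    r32 = A$r13 * B$r12 + A$r23 * B$r22 + A$r33 * B$r32,
    r33 = A$r13 * B$r13 + A$r23 * B$r23 + A$r33 * B$r33
  )
}

# Euler XYZ decomposition from rotation components (vectorized), degrees.
# R = Rx(x) Ry(y) Rz(z):
#   R[1,3] = sin(y); R[2,3] = -sin(x)cos(y); R[3,3] = cos(x)cos(y)
#   R[1,2] = -cos(y)sin(z); R[1,1] = cos(y)cos(z)
euler_xyz_components <- function(rc) {
  y <- asin(pmin(pmax(rc$r13, -1), 1))
  x <- atan2(-rc$r23, rc$r33)
  z <- atan2(-rc$r12, rc$r11)
  deg <- 180 / pi
  list(x = x * deg, y = y * deg, z = z * deg,
       gimbal = abs(y * deg) > 89)
}

#' Euler XYZ decomposition of a rotation matrix
#'
#' Returns angles (degrees) such that `R = Rx(x) %*% Ry(y) %*% Rz(z)`, on the
#' canonical branch with y in (-90, 90) degrees. Proximity to gimbal lock
#' (|y| > 89 degrees) is flagged via a warning.
#'
#' @param R 3 x 3 rotation matrix (orthonormal, det +1).
#' @param tol Orthonormality tolerance.
#' @return Named numeric vector `c(x=, y=, z=)`, degrees.
#' @export
euler_xyz <- function(R, tol = 1e-6) {
  if (!is.matrix(R) || !all(dim(R) == c(3, 3)))
    stop("R must be a 3 x 3 matrix")
  if (max(abs(crossprod(R) - diag(3))) > tol || det(R) < 0)
    stop("R is not a rotation matrix")
  rc <- list(r11 = R[1, 1], r12 = R[1, 2], r13 = R[1, 3],
             r23 = R[2, 3], r33 = R[3, 3])
  e <- euler_xyz_components(rc)
  if (e$gimbal) warning("rotation is near gimbal lock (|y| > 89 deg)")
  c(x = e$x, y = e$y, z = e$z)
}

#' Compose a rotation matrix from Euler XYZ angles
#'
#' Inverse of [euler_xyz()]: `Rx(x) %*% Ry(y) %*% Rz(z)`, angles in degrees.
#'
#' @param angles Numeric 3-vector (x, y, z), degrees.
#' @return 3 x 3 rotation matrix.
#' @export
compose_euler_xyz <- function(angles) {
  a <- angles * pi / 180
  cx <- cos(a[1]); sx <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cz <- cos(a[3]); sz <- sin(a[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Rx %*% Ry %*% Rz
}

marker_matrix <- function(seq, label) {
  if (!(label %in% marker_labels(seq)))
    stop("marker sequence lacks required marker: ", label)
  m <- seq$positions[, , label, drop = TRUE]
  if (is.null(dim(m))) m <- matrix(m, nrow = 1)
  if (any(is.na(m)))
    stop("marker ", label, " has unfilled gaps; run interpolate_gaps() first")
  m
}

pelvis_frames <- function(seq, def) {
  psis_l <- marker_matrix(seq, def$origin_left)
  psis_r <- marker_matrix(seq, def$origin_right)
  asis_l <- marker_matrix(seq, def$ml_left)
  asis_r <- marker_matrix(seq, def$ml_right)
  crest_l <- marker_matrix(seq, def$si_left)
  crest_r <- marker_matrix(seq, def$si_right)
  origin <- (psis_l + psis_r) / 2
  ml <- asis_r - asis_l
  ml <- ml / sqrt(rowSums(ml^2))
  up <- (crest_l + crest_r) / 2 - origin
  si <- up - rowSums(up * ml) * ml
  si <- si / sqrt(rowSums(si^2))
  pa <- cbind(ml[, 2] * si[, 3] - ml[, 3] * si[, 2],
              ml[, 3] * si[, 1] - ml[, 1] * si[, 3],
              ml[, 1] * si[, 2] - ml[, 2] * si[, 1])
  list(origin = origin,
       r11 = ml[, 1], r21 = ml[, 2], r31 = ml[, 3],
       r12 = si[, 1], r22 = si[, 2], r32 = si[, 3],
       r13 = pa[, 1], r23 = pa[, 2], r33 = pa[, 3])
}

#' Compute upper- and lower-lumbar Euler angle series
#'
#' Per frame, builds the upper lumbar (L1 lateral pair + L3), lower lumbar
#' (L4 lateral pair + L5), and pelvis (PSIS/ASIS/crest pairs) segment frames,
#' forms the relative rotations upper-relative-to-lower
#' (`t(R_lower) %*% R_upper`) and lower-relative-to-pelvis
#' (`t(R_pelvis) %*% R_lower`), and decomposes each with the Euler XYZ
#' sequence. Axis roles: X about ML (flexion/extension), Y about SI (axial
#' rotation), Z about PA (lateral bend).
#'
#' Optionally, marker trajectories are low-pass filtered before frame
#' construction (4th-order zero-phase Butterworth), the standard treatment of
#' broadband marker jitter in marker-based kinematics. Off by default: trunk
#' movement lives below ~1 Hz, so a 6 Hz cutoff is conventional when enabled.
#'
#' @param seq A gap-free [marker_seq()].
#' @param model Segment definitions, see [spine_model_definition()].
#' @param lowpass_hz Optional Butterworth cutoff, Hz (`NULL` = no filtering).
#' @return Data frame of class `"kinematic_angles"`: `t` plus columns
#'   `upper_x`, `upper_y`, `upper_z`, `lower_x`, `lower_y`, `lower_z`
#'   (degrees).
#' @export
compute_lumbar_angles <- function(seq, model = spine_model_definition(),
                                  lowpass_hz = NULL) {
  stopifnot(inherits(seq, "marker_seq"))
  if (!is.null(lowpass_hz)) seq <- lowpass_markers(seq, lowpass_hz)
  up <- model$upper_lumbar
  lo <- model$lower_lumbar
  F_up <- frames_from_markers(marker_matrix(seq, up$lateral_left),
                              marker_matrix(seq, up$lateral_right),
                              marker_matrix(seq, up$inferior))
  F_lo <- frames_from_markers(marker_matrix(seq, lo$lateral_left),
                              marker_matrix(seq, lo$lateral_right),
                              marker_matrix(seq, lo$inferior))
  F_pel <- pelvis_frames(seq, model$pelvis)
  e_up <- euler_xyz_components(relative_rotation_components(F_lo, F_up))
  e_lo <- euler_xyz_components(relative_rotation_components(F_pel, F_lo))
  out <- data.frame(t = seq$t,
                    upper_x = e_up$x, upper_y = e_up$y, upper_z = e_up$z,
                    lower_x = e_lo$x, lower_y = e_lo$y, lower_z = e_lo$z)
  class(out) <- c("kinematic_angles", class(out))
  out
}

#' Primary-plane angle column for a movement
#'
#' The study reports a single upper/lower lumbar angle per movement; the
#' pipeline uses the Euler component of the movement's primary plane
#' (x for flexion/extension, y for axial rotation, z for lateral bending).
#'
#' @param movement One of [movement_levels()].
#' @param segment `"upper_lumbar"` or `"lower_lumbar"`.
#' @return Column name into a `kinematic_angles` data frame.
#' @export
primary_angle_column <- function(movement, segment) {
  comp <- movement_axis(movement)$component
  prefix <- switch(segment, upper_lumbar = "upper", lower_lumbar = "lower",
                   stop("unknown segment: ", segment))
  paste0(prefix, "_", comp)
}
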