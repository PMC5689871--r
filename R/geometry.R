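# Coordinate frames and divergent projection.
#
# Room frame: origin at isocenter; at all angles zero +y points from the
# source towards the isocenter (beam direction), +x is the X-jaw / MLC travel
# direction, +z the Y-jaw direction (couch long axis).  The gantry rotates
# about z, the couch about y, and the collimator in the (u, w) portal plane.

#' Beam angle set
#'
#' Bundles the couch, gantry and collimator angles of a beam state.  Angles
#' are stored in degrees; any real value is accepted and normalised into
#' `[0, 360)` on storage (the DICOM convention).  Use
#' [signed_angle()] to obtain the continuous signed representation in
#' `(-180, 180]` used for interpolation across the 0/360 seam.
#'
#' @param couch_deg,gantry_deg,collimator_deg angles in degrees.
#' @return an object of class `beam_angles` (named numeric vector).
#' @export
beam_angles <- function(couch_deg = 0, gantry_deg = 0, collimator_deg = 0) {
  a <- c(couch_deg = as.numeric(couch_deg) %% 360,
         gantry_deg = as.numeric(gantry_deg) %% 360,
         collimator_deg = as.numeric(collimator_deg) %% 360)
  stopifnot(all(is.finite(a)))
  structure(a, class = "beam_angles")
}

#' Signed angle representation
#'
#' Maps angles (degrees) to the continuous signed representation in
#' `(-180, 180]`, so that shortest-arc differences and interpolation behave
#' across the 0/360 seam.
#'
#' @param deg numeric vector of angles in degrees.
#' @return numeric vector in `(-180, 180]`.
#' @export
signed_angle <- function(deg) {
  s <- deg %% 360
  s[s > 180] <- s[s > 180] - 360
  s
}

#' Shortest-arc signed difference `a - b` in degrees, in `(-180, 180]`.
#' @param a,b angles in degrees.
#' @return signed difference in degrees.
#' @export
angle_diff <- function(a, b) signed_angle(a - b)

#' Circular mean of angles in degrees
#'
#' Mean direction of a set of angles, used when merging delivery-log records
#' whose gantry readings may straddle the 0/360 seam.
#'
#' @param deg numeric vector of angles (degrees).
#' @return mean angle in `[0, 360)`.
#' @export
circular_mean_deg <- function(deg) {
  r <- deg * pi / 180
  m <- (atan2(mean(sin(r)), mean(cos(r))) * 180 / pi) %% 360
  if (m >= 360 - 1e-9) 0 else m
}

deg2rad <- function(d) d * pi / 180

# Rotation about z (gantry axis): maps (0,-1,0) to sin/cos combinations in
# the x-y plane; the room stays right-handed.
rot_z <- function(deg) {
  c <- cos(deg2rad(deg)); s <- sin(deg2rad(deg))
  matrix(c(c, -s, 0, s, c, 0, 0, 0, 1), nrow = 3, byrow = TRUE)
}

# Rotation about y (couch axis).
rot_y <- function(deg) {
  c <- cos(deg2rad(deg)); s <- sin(deg2rad(deg))
  matrix(c(c, 0, s, 0, 1, 0, -s, 0, c), nrow = 3, byrow = TRUE)
}

#' Rotate a room-frame point into the beam frame
#'
#' Expresses a point in the gantry-0 / couch-0 beam frame by applying the
#' inverse couch then inverse gantry rotation, `R_g(-beta) R_couch(-alpha) r`.
#' The collimator rotation is applied later, in portal space, by
#' [project_to_portal()].
#'
#' @param p numeric length-3 room-frame point (cm), or a 3-row matrix of
#'   column points.
#' @param angles a [beam_angles()] object.
#' @return point(s) in the beam frame, same shape as `p`.
#' @export
rotate_to_beam_frame <- function(p, angles) {
  R <- rot_z(-angles[["gantry_deg"]]) %*% rot_y(-angles[["couch_deg"]])
  if (is.matrix(p)) R %*% p else as.numeric(R %*% p)
}

#' Project a beam-frame point onto the portal plane
#'
#' Divergent (point-source) projection onto the plane through the isocenter
#' at distance `SAD` from the source, followed by the in-plane collimator
#' rotation: `u0 = x * SAD / (y + SAD)`, `w0 = z * SAD / (y + SAD)`, then
#' `(u, w) = R_col(theta) (u0, w0)`.
#'
#' @param p beam-frame point (length-3 numeric, cm) or 3-row matrix.
#' @param collimator_deg collimator angle theta in degrees.
#' @param SAD source-to-axis distance in cm (default 100).
#' @return named numeric `c(u, w)` in cm, or a 2-row matrix.
#' @export
project_to_portal <- function(p, collimator_deg = 0, SAD = 100) {
  stopifnot(SAD > 0)
  m <- if (is.matrix(p)) p else matrix(p, nrow = 3)
  y <- m[2, ]
  if (any(y <= -SAD + 1e-6))
    stop("behind source: point(s) at or upstream of the source plane (y <= -SAD)")
  f <- SAD / (y + SAD)
  u0 <- m[1, ] * f
  w0 <- m[3, ] * f
  th <- deg2rad(collimator_deg)
  u <- cos(th) * u0 - sin(th) * w0
  w <- sin(th) * u0 + cos(th) * w0
  if (is.matrix(p)) rbind(u = u, w = w) else c(u = u, w = w)
}

#' Source position in the room frame
#'
#' Position of the x-ray point source for a given beam state: the beam-frame
#' source `(0, -SAD, 0)` carried back to the room frame by the couch and
#' gantry rotations.  Its distance to the isocenter is always `SAD`.
#'
#' @inheritParams rotate_to_beam_frame
#' @param SAD source-to-axis distance (cm).
#' @return length-3 numeric room-frame position (cm).
#' @export
source_position <- function(angles, SAD = 100) {
  stopifnot(SAD > 0)
  R <- rot_y(angles[["couch_deg"]]) %*% rot_z(angles[["gantry_deg"]])
  as.numeric(R %*% c(0, -SAD, 0))
}

#' Mean of two source positions
#'
#' Arithmetic mean of the source positions at two beam states, used as the
#' effective source of a plan segment spanning two control points.  For
#' distinct states the mean lies strictly inside the SAD sphere.
#'
#' @param a,b [beam_angles()] objects at the segment end points.
#' @param SAD source-to-axis distance (cm).
#' @return length-3 numeric room-frame position (cm).
#' @export
mean_source_position <- function(a, b, SAD = 100) {
  (source_position(a, SAD) + source_position(b, SAD)) / 2
}
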