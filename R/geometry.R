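# Low-level geometry: quaternions, rotations, dihedrals, internal-coordinate
# atom placement. All coordinates in Angstrom, all angles in radians.

#' Normalize a quaternion
#'
#' @param q numeric length-4 vector `(w, x, y, z)`.
#' @return unit quaternion.
#' @keywords internal
quat_normalize <- function(q) {
  n <- sqrt(sum(q^2))
  if (n < 1e-12) stop("degenerate quaternion (norm ~ 0)")
  q / n
}

#' Quaternion from axis-angle
#' @param axis length-3 vector (need not be unit).
#' @param angle rotation angle, radians.
#' @keywords internal
quat_from_axis_angle <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  c(cos(angle / 2), sin(angle / 2) * axis)
}

#' Compose two quaternions (q1 applied after q2)
#' @keywords internal
quat_multiply <- function(q1, q2) {
  w1 <- q1[1]; v1 <- q1[2:4]
  w2 <- q2[1]; v2 <- q2[2:4]
  c(w1 * w2 - sum(v1 * v2),
    w1 * v2 + w2 * v1 + c(
      v1[2] * v2[3] - v1[3] * v2[2],
      v1[3] * v2[1] - v1[1] * v2[3],
      v1[1] * v2[2] - v1[2] * v2[1]))
}

#' Rotation matrix of a unit quaternion
#' @keywords internal
quat_to_matrix <- function(q) {
  q <- quat_normalize(q)
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
    nrow = 3, byrow = TRUE)
}

#' Uniform random unit quaternion (Marsaglia / subgroup algorithm)
#' @keywords internal
quat_random <- function() {
  u <- runif(3)
  c(sqrt(1 - u[1]) * sin(2 * pi * u[2]),
    sqrt(1 - u[1]) * cos(2 * pi * u[2]),
    sqrt(u[1]) * sin(2 * pi * u[3]),
    sqrt(u[1]) * cos(2 * pi * u[3]))
}

#' Rotate points about an arbitrary axis
#'
#' @param xyz n x 3 matrix of points to rotate.
#' @param p1,p2 two points defining the axis (rotation about the line p1->p2).
#' @param angle radians, right-handed about p1->p2.
#' @return rotated n x 3 matrix.
#' @keywords internal
rotate_about_axis <- function(xyz, p1, p2, angle) {
  R <- quat_to_matrix(quat_from_axis_angle(p2 - p1, angle))
  sweep(sweep(xyz, 2, p1) %*% t(R), 2, p1, `+`)
}

#' Signed dihedral angle of four points
#'
#' Returns the torsion p1-p2-p3-p4 in (-pi, pi], the IUPAC sign convention.
#'
#' @param p1,p2,p3,p4 length-3 coordinate vectors.
#' @return angle in radians.
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  atan2(sum(m1 * n2), sum(n1 * n2))
}

#' Place an atom from internal coordinates (NeRF)
#'
#' Positions a new atom at distance `bond` from `p3`, with angle
#' `angle` at p3 between the new atom and p2, and dihedral `dihedral`
#' around the p2->p3 axis relative to p1.
#'
#' @param p1,p2,p3 previously placed coordinates.
#' @param bond bond length, Angstrom.
#' @param angle bond angle, radians.
#' @param dihedral torsion, radians.
#' @return length-3 coordinates of the new atom.
#' @keywords internal
place_atom <- function(p1, p2, p3, bond, angle, dihedral) {
  bc <- p3 - p2; bc <- bc / sqrt(sum(bc^2))
  ab <- p2 - p1
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d <- c(-bond * cos(angle),
         bond * sin(angle) * cos(dihedral),
         bond * sin(angle) * sin(dihedral))
  p3 + d[1] * bc + d[2] * m + d[3] * n
}
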