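## Small 3-D geometry kernel: internal-coordinate atom placement (NeRF),
## bond/torsion angles, axis rotations. Coordinates are Angstrom throughout.

.vnorm <- function(v) sqrt(sum(v * v))

.unit <- function(v) {
  n <- .vnorm(v)
  if (n < 1e-12) stop("cannot normalise a zero vector")
  v / n
}

.cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Bond angle between three points
#'
#' @param a,b,c numeric length-3 coordinates; the angle is at `b`.
#' @return Angle in degrees in `[0, 180]`.
#' @keywords internal
bond_angle <- function(a, b, c) {
  u <- .unit(a - b); v <- .unit(c - b)
  acos(max(-1, min(1, sum(u * v)))) * 180 / pi
}

#' Torsion (dihedral) angle of four points
#'
#' Signed torsion a-b-c-d using the IUPAC convention.
#'
#' @param a,b,c,d numeric length-3 coordinates.
#' @return Angle in degrees in `(-180, 180]`.
#' @keywords internal
torsion_angle <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- .cross(b1, b2); n2 <- .cross(b2, b3)
  m1 <- .cross(n1, .unit(b2))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

#' Place an atom from internal coordinates (NeRF)
#'
#' Positions a new atom `d` so that |d - c| = `bond`, the angle b-c-d equals
#' `angle` and the torsion a-b-c-d equals `torsion`.
#'
#' @param a,b,c reference coordinates (length-3).
#' @param bond bond length in Angstrom.
#' @param angle bond angle in degrees.
#' @param torsion torsion angle in degrees.
#' @return Length-3 coordinate of the placed atom.
#' @keywords internal
place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  bc <- .unit(c - b)
  n  <- .unit(.cross(b - a, bc))
  m  <- .cross(n, bc)
  d2 <- bond * c(-cos(ang), sin(ang) * cos(tor), -sin(ang) * sin(tor))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

#' Rotation matrix about an arbitrary axis
#'
#' Rodrigues rotation matrix for a right-handed rotation of `theta` degrees
#' about the unit vector `axis`.
#'
#' @param axis length-3 vector (normalised internally).
#' @param theta rotation angle in degrees.
#' @return A 3x3 rotation matrix.
#' @keywords internal
rotation_matrix <- function(axis, theta) {
  u <- .unit(axis)
  th <- theta * pi / 180
  ct <- cos(th); st <- sin(th)
  ux <- matrix(c(0, -u[3], u[2],
                 u[3], 0, -u[1],
                 -u[2], u[1], 0), 3, 3, byrow = TRUE)
  ct * diag(3) + st * ux + (1 - ct) * (u %o% u)
}

## Rotate rows of an n x 3 coordinate matrix about `axis` through `center`.
.rotate_coords <- function(xyz, axis, theta, center = c(0, 0, 0)) {
  R <- rotation_matrix(axis, theta)
  sweep(sweep(xyz, 2, center) %*% t(R), 2, center, "+")
}
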