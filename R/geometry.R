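# Internal vector geometry used by structure construction and analysis.
# All coordinates are in Angstrom; angles in degrees unless noted.

vnorm <- function(v) sqrt(sum(v * v))

unit_vec <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("degenerate (zero-length) vector")
  v / n
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Dihedral angle of four points
#'
#' Torsion angle a-b-c-d with the IUPAC sign convention: looking from b to c,
#' a clockwise rotation of the far bond is positive. Returned in degrees in
#' (-180, 180].
#'
#' @param a,b,c,d numeric length-3 coordinate vectors (Angstrom).
#' @return Dihedral angle in degrees.
#' @keywords internal
dihedral_angle <- function(a, b, c, d) {
  b1 <- b - a
  b2 <- c - b
  b3 <- d - c
  n1 <- pracma_cross(b1, b2)
  n2 <- pracma_cross(b2, b3)
  m1 <- pracma_cross(n1, unit_vec(b2))
  x <- sum(n1 * n2)
  y <- -sum(m1 * n2)
  ang <- rad2deg(atan2(y, x))
  if (ang <= -180) ang <- ang + 360
  ang
}

# cross product (named to avoid masking; base R has none)
pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

angle_between <- function(u, v) {
  cu <- unit_vec(u); cv <- unit_vec(v)
  rad2deg(acos(max(-1, min(1, sum(cu * cv)))))
}

#' Place an atom from internal coordinates (NeRF)
#'
#' Position a point d with bond length |c-d|, bond angle b-c-d and torsion
#' a-b-c-d, the standard natural-extension-of-reference-frame construction.
#'
#' @param a,b,c reference coordinates (length-3).
#' @param bond bond length c-d (Angstrom).
#' @param angle bond angle b-c-d (degrees).
#' @param torsion dihedral a-b-c-d (degrees).
#' @return length-3 coordinates of the placed atom.
#' @keywords internal
place_atom <- function(a, b, c, bond, angle, torsion) {
  th <- deg2rad(angle)
  ph <- deg2rad(torsion)
  bc <- unit_vec(c - b)
  n <- unit_vec(pracma_cross(b - a, bc))
  m <- pracma_cross(n, bc)
  d2 <- bond * c(-cos(th), sin(th) * cos(ph), sin(th) * sin(ph))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

#' Random rigid motion
#'
#' Draw a uniformly random proper rotation (QR of a Gaussian matrix, sign
#' fixed) and a random translation; used for rigid-invariance checks.
#'
#' @param translation_scale standard deviation of the translation (Angstrom).
#' @return list with 3x3 rotation matrix `R` and length-3 translation `t`.
#' @export
random_rigid_motion <- function(translation_scale = 20) {
  m <- matrix(stats::rnorm(9), 3, 3)
  qr_ <- qr(m)
  R <- qr.Q(qr_)
  d <- diag(qr.R(qr_))
  R <- R %*% diag(sign(d))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  list(R = R, t = stats::rnorm(3, sd = translation_scale))
}

#' Apply a rigid motion to a structure
#'
#' @param structure a [Structure] object.
#' @param motion list with rotation `R` and translation `t`, as returned by
#'   [random_rigid_motion()].
#' @return the transformed [Structure].
#' @export
transform_structure <- function(structure, motion) {
  stopifnot(inherits(structure, "Structure"))
  xyz <- as.matrix(structure$atoms[, c("x", "y", "z")])
  xyz <- xyz %*% t(motion$R)
  xyz <- sweep(xyz, 2, motion$t, "+")
  structure$atoms$x <- xyz[, 1]
  structure$atoms$y <- xyz[, 2]
  structure$atoms$z <- xyz[, 3]
  structure
}
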