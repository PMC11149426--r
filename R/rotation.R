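#' @useDynLib bioeye, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats approx aggregate anova coef cor lm lm.fit median optim
#'   predict pnorm quantile resid rnorm runif sd setNames rexp
#' @importFrom utils modifyList read.csv write.csv head tail
NULL

#' Vector cross product
#'
#' @param a,b numeric length-3 vectors.
#' @return `a x b` as a numeric length-3 vector.
#' @keywords internal
cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

as_rotvec <- function(r) {
  r <- as.numeric(r)
  if (length(r) != 3L || !all(is.finite(r)))
    stop("a rotation vector must be 3 finite numbers (rad/2 units)", call. = FALSE)
  r
}

#' Angular velocity from orientation rate
#'
#' Eye orientations are held as Euler-Rodrigues rotation vectors
#' `r = tan(theta/2) * n` (units rad/2) in a right-handed head-fixed frame:
#' x frontal (clockwise torsion positive), y horizontal axis (downward
#' rotation positive), z vertical axis (leftward rotation positive). The
#' angular velocity about the momentary rotation axis relates to the rate of
#' change of the rotation vector (the coordinate velocity) through a
#' non-commutative cross-product term:
#' `omega = 2 (rdot + r x rdot) / (1 + |r|^2)`.
#'
#' @param r rotation vector (rad/2).
#' @param rdot its time derivative (rad/2 per s).
#' @return angular velocity, rad/s, length-3 numeric.
#' @seealso [rdot_from_omega()] for the exact inverse.
#' @export
#' @examples
#' omega_from_rdot(c(0, 0, 0), c(0, 0, 0.1))   # 2*rdot at reference
omega_from_rdot <- function(r, rdot) {
  r <- as_rotvec(r); rdot <- as.numeric(rdot)
  2 * (rdot + cross3(r, rdot)) / (1 + sum(r^2))
}

#' Orientation rate from angular velocity
#'
#' Exact algebraic inverse of [omega_from_rdot()]:
#' `2 rdot = omega + omega x r + (omega . r) r`.
#'
#' @param r rotation vector (rad/2).
#' @param w angular velocity (rad/s).
#' @return coordinate velocity `rdot`, rad/2 per s.
#' @export
rdot_from_omega <- function(r, w) {
  r <- as_rotvec(r); w <- as.numeric(w)
  0.5 * (w + cross3(w, r) + sum(w * r) * r)
}

#' Compose two rotations in rotation-vector form
#'
#' Returns the rotation vector of "first `r_a`, then `r_b`":
#' `(r_b + r_a + r_b x r_a) / (1 - r_b . r_a)`. The product is
#' non-commutative. The denominator vanishes when the composed rotation
#' reaches 180 degrees, far outside the oculomotor range; that case errors
#' rather than being regularized.
#'
#' @param r_b,r_a rotation vectors (rad/2); `r_a` is applied first.
#' @return rotation vector of the composition.
#' @export
rot_compose <- function(r_b, r_a) {
  r_b <- as_rotvec(r_b); r_a <- as_rotvec(r_a)
  den <- 1 - sum(r_b * r_a)
  if (abs(den) < 1e-12)
    stop("rotation composition degenerate: combined angle reaches 180 deg", call. = FALSE)
  (r_b + r_a + cross3(r_b, r_a)) / den
}

#' Relative rotation carrying one orientation onto another
#'
#' The rotation `q` with `q o r_on = r_G` (composition as in
#' [rot_compose()]), i.e. the eye displacement that brings orientation
#' `r_on` to goal `r_G`:
#' `q = (r_G - r_on + r_on x r_G) / (1 + r_on . r_G)`.
#' This is the rotation-vector image of the quaternion quotient
#' `q_G (x) q_on^-1`; the denominator sign is fixed by the requirement that
#' the composition identity hold exactly, which the test suite checks
#' against a quaternion oracle. Used to express chained-paradigm goals as
#' true rotational displacements.
#'
#' @param r_on initial orientation (rad/2).
#' @param r_G goal orientation (rad/2).
#' @return rotation vector of the displacement.
#' @export
rot_between <- function(r_on, r_G) {
  r_on <- as_rotvec(r_on); r_G <- as_rotvec(r_G)
  den <- 1 + sum(r_on * r_G)
  if (abs(den) < 1e-12)
    stop("relative rotation degenerate: orientations 180 deg apart", call. = FALSE)
  (r_G - r_on + cross3(r_on, r_G)) / den
}

#' Rotation matrix of a rotation vector
#'
#' @param r rotation vector (rad/2).
#' @return 3x3 rotation matrix acting on head-frame coordinates.
#' @export
rot_matrix <- function(r) {
  r <- as_rotvec(r)
  s2 <- 1 + sum(r^2)
  rx <- matrix(c(0, r[3], -r[2],
                 -r[3], 0, r[1],
                 r[2], -r[1], 0), 3, 3)
  diag(3) + (2 / s2) * (rx + rx %*% rx)
}

#' Rotation angle of a rotation vector
#'
#' @param r rotation vector (rad/2).
#' @return the rotation angle `2*atan(|r|)` in degrees.
#' @export
rot_angle <- function(r) {
  r <- as_rotvec(r)
  2 * atan(sqrt(sum(r^2))) * 180 / pi
}

#' Gaze angles of an eye orientation
#'
#' Azimuth (rightward positive) and elevation (upward positive) in degrees:
#' `azimuth = -2 atan(r_z)`, `elevation = -2 atan(r_y)`. These invert the
#' leftward-positive / downward-positive axis conventions of the rotation
#' vector so that the angles follow the usual perimetric signs.
#'
#' @param r rotation vector (rad/2), or an n x 3 matrix of them.
#' @return named numeric `c(azimuth=, elevation=)` in degrees, or an n x 2
#'   matrix for matrix input.
#' @export
gaze_angles <- function(r) {
  if (is.matrix(r)) {
    out <- cbind(azimuth = -2 * atan(r[, 3]) * 180 / pi,
                 elevation = -2 * atan(r[, 2]) * 180 / pi)
    return(out)
  }
  r <- as_rotvec(r)
  c(azimuth = -2 * atan(r[3]) * 180 / pi,
    elevation = -2 * atan(r[2]) * 180 / pi)
}

#' Rotation vector from gaze angles
#'
#' Inverse of [gaze_angles()] on the (azimuth, elevation) subspace. Torsion
#' is not determined by gaze direction (that is precisely what Listing's law
#' constrains) and is supplied explicitly, default zero.
#'
#' @param azimuth,elevation gaze angles in degrees.
#' @param rx torsional component (rad/2), default 0.
#' @return rotation vector (rad/2).
#' @export
rotvec_from_gaze <- function(azimuth, elevation, rx = 0) {
  c(rx,
    -tan(elevation * pi / 360),
    -tan(azimuth * pi / 360))
}

#' Half-angle rule tilt
#'
#' For a horizontal eye movement made from vertical eccentricity `phi0` with
#' the coordinate velocity confined to Listing's plane, the angular velocity
#' axis tilts out of the plane by half the eccentricity: `rho = phi0 / 2`.
#' This follows directly from the cross-product term of
#' [omega_from_rdot()] with `r_on = tan(phi0/2) * y` and `rdot` along z.
#'
#' @param phi0 vertical eccentricity in degrees.
#' @return tilt angle between the angular and coordinate velocity axes, degrees.
#' @export
half_angle_tilt <- function(phi0) {
  phi0 / 2
}
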