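# Unit-quaternion helpers for rigid-water orientations.
#
# Quaternions are stored as length-4 numeric vectors (w, x, y, z) or as
# n x 4 matrices, always unit norm.  The double cover of SO(3) is handled
# downstream by taking |q1 . q2| in distances.

#' Uniform random unit quaternions (Shoemake's method)
#'
#' @param n number of quaternions.
#' @return an `n x 4` matrix of unit quaternions, rows `(w, x, y, z)`.
#' @export
random_quaternions <- function(n) {
  u1 <- stats::runif(n)
  u2 <- stats::runif(n)
  u3 <- stats::runif(n)
  s1 <- sqrt(1 - u1)
  s2 <- sqrt(u1)
  cbind(
    s1 * sin(2 * pi * u2),
    s1 * cos(2 * pi * u2),
    s2 * sin(2 * pi * u3),
    s2 * cos(2 * pi * u3)
  )
}

#' Rotation matrix from a unit quaternion
#' @param q unit quaternion `(w, x, y, z)`.
#' @return a 3 x 3 rotation matrix.
#' @keywords internal
quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

#' Rotate points by a unit quaternion
#' @param q unit quaternion.
#' @param X `n x 3` matrix of coordinates.
#' @keywords internal
quat_rotate <- function(q, X) {
  X %*% t(quat_to_matrix(q))
}

#' Geodesic distance between orientations
#'
#' Distance is the rotation angle `2 * acos(|q1 . q2|)` in radians, in
#' `[0, pi]`; the absolute dot product folds the quaternion double cover.
#'
#' @param q1,q2 unit quaternions.
#' @return rotation angle in radians.
#' @export
quat_distance <- function(q1, q2) {
  d <- abs(sum(q1 * q2))
  2 * acos(min(1, d))
}

#' Compose two quaternions (q1 then q2 applied: q2 * q1)
#' @keywords internal
quat_multiply <- function(q2, q1) {
  w1 <- q1[1]; v1 <- q1[2:4]
  w2 <- q2[1]; v2 <- q2[2:4]
  c(
    w2 * w1 - sum(v2 * v1),
    w2 * v1 + w1 * v2 + c(
      v2[2] * v1[3] - v2[3] * v1[2],
      v2[3] * v1[1] - v2[1] * v1[3],
      v2[1] * v1[2] - v2[2] * v1[1]
    )
  )
}

#' Quaternion for a rotation about an axis
#' @param axis 3-vector (normalised internally).
#' @param angle rotation angle in radians.
#' @keywords internal
axis_angle_quat <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  c(cos(angle / 2), sin(angle / 2) * axis)
}

#' Concentrated random orientations about a mode
#'
#' Samples orientations as the mode quaternion composed with a random
#' rotation whose axis is uniform on the sphere and whose angle is
#' `|N(0, sd_angle)|` truncated to `[0, pi]`.  Used by the synthetic GIST
#' generator to plant orientationally ordered water populations.
#'
#' @param n number of samples.
#' @param mode unit quaternion at the centre of the distribution.
#' @param sd_angle standard deviation of the rotation angle, radians.
#' @return `n x 4` matrix of unit quaternions.
#' @export
concentrated_quaternions <- function(n, mode = c(1, 0, 0, 0), sd_angle = 0.2) {
  stopifnot(sd_angle >= 0)
  psi <- pmin(abs(stats::rnorm(n, 0, sd_angle)), pi)
  z <- stats::runif(n, -1, 1)
  phi <- stats::runif(n, 0, 2 * pi)
  sz <- sqrt(1 - z^2)
  out <- matrix(0, n, 4)
  for (i in seq_len(n)) {
    dq <- axis_angle_quat(c(sz[i] * cos(phi[i]), sz[i] * sin(phi[i]), z[i]), psi[i])
    out[i, ] <- quat_multiply(dq, mode)
  }
  out
}
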