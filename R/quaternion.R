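# Quaternion utilities shared by the geometry builders, the engine wrappers
# and the trajectory analytics. Convention: q = (w, x, y, z), unit norm,
# R(q) rotates body-frame vectors into the world frame.

#' Rotation matrix from a unit quaternion
#'
#' @param q numeric length-4 quaternion `(w, x, y, z)`.
#' @return 3x3 rotation matrix mapping body-frame to world-frame coordinates.
#' @keywords internal
quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

#' Unit quaternion from a rotation matrix
#' @param R proper rotation matrix (det +1).
#' @return numeric length-4 quaternion `(w, x, y, z)`.
#' @keywords internal
matrix_to_quat <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else if (R[1, 1] >= R[2, 2] && R[1, 1] >= R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s, (R[1, 2] + R[2, 1]) / s,
           (R[1, 3] + R[3, 1]) / s)
  } else if (R[2, 2] >= R[3, 3]) {
    s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s, 0.25 * s,
           (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
           (R[2, 3] + R[3, 2]) / s, 0.25 * s)
  }
  q / sqrt(sum(q^2))
}

#' Rotate body-frame points into the world frame
#'
#' @param q unit quaternion `(w, x, y, z)`.
#' @param X n x 3 matrix of body-frame points.
#' @return n x 3 matrix of rotated points.
#' @keywords internal
quat_rotate <- function(q, X) {
  X <- matrix(X, ncol = 3)
  X %*% t(quat_to_matrix(q))
}

#' Hamilton product of two quaternions
#' @keywords internal
quat_multiply <- function(a, b) {
  c(a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1])
}

#' Uniform random unit quaternions
#'
#' Draws orientations uniformly on SO(3) (Shoemake's subgroup algorithm),
#' consuming the R random stream.
#'
#' @param n number of quaternions.
#' @return n x 4 matrix of unit quaternions.
#' @keywords internal
random_quaternions <- function(n) {
  u1 <- stats::runif(n); u2 <- stats::runif(n); u3 <- stats::runif(n)
  cbind(sqrt(1 - u1) * sin(2 * pi * u2),
        sqrt(1 - u1) * cos(2 * pi * u2),
        sqrt(u1) * sin(2 * pi * u3),
        sqrt(u1) * cos(2 * pi * u3))
}
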