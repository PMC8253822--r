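#' zxz Euler angles and rotation matrices
#'
#' Rotations are parameterized in the zxz convention used throughout
#' subtomogram averaging: \code{R = Rz(psi) \%*\% Rx(theta) \%*\% Rz(phi)},
#' mapping body-frame vectors into the lab frame. With this convention the
#' body +z axis is carried onto the direction
#' \code{(sin(theta) sin(psi), -sin(theta) cos(psi), cos(theta))}, so for a
#' pose whose body z axis lies along a filament tangent, \code{phi} is the
#' in-plane rotation about the filament axis.
#'
#' @param phi,theta,psi angles in degrees.
#' @return \code{euler_to_matrix}: a 3x3 rotation matrix.
#' @export
euler_to_matrix <- function(phi, theta, psi) {
  d <- pi / 180
  rz <- function(a) {
    c <- cos(a * d); s <- sin(a * d)
    matrix(c(c, s, 0, -s, c, 0, 0, 0, 1), 3, 3)
  }
  rx <- function(a) {
    c <- cos(a * d); s <- sin(a * d)
    matrix(c(1, 0, 0, 0, c, s, 0, -s, c), 3, 3)
  }
  rz(psi) %*% rx(theta) %*% rz(phi)
}

#' @rdname euler_to_matrix
#' @param R a 3x3 rotation matrix.
#' @return \code{matrix_to_euler}: named numeric vector (phi, theta, psi) in
#'   degrees, with \code{phi} wrapped to [0, 360) and \code{psi = 0} in the
#'   gimbal-degenerate case \code{theta ~ 0 or 180}.
#' @export
matrix_to_euler <- function(R) {
  d <- 180 / pi
  ct <- max(-1, min(1, R[3, 3]))
  theta <- acos(ct) * d
  if (abs(ct) > 1 - 1e-12) {
    # theta ~ 0 (or 180): phi and psi degenerate; put everything in phi
    phi <- atan2(R[2, 1], R[1, 1]) * d * sign(ct)
    psi <- 0
  } else {
    phi <- atan2(R[3, 1], R[3, 2]) * d
    psi <- atan2(R[1, 3], -R[2, 3]) * d
  }
  c(phi = phi %% 360, theta = theta, psi = psi)
}

#' Orientation angles carrying the body z axis onto a tangent
#'
#' Returns the (theta, psi) pair such that the zxz rotation
#' \code{euler_to_matrix(phi, theta, psi)} maps the unit z axis onto the unit
#' tangent \code{t}, for any phi. theta is the polar angle of the tangent
#' from +z; psi fixes its azimuth (psi = 0 when the tangent is parallel to z).
#'
#' @param t unit 3-vector.
#' @return named vector (theta, psi) in degrees.
#' @export
tangent_to_euler <- function(t) {
  t <- t / sqrt(sum(t^2))
  d <- 180 / pi
  ct <- max(-1, min(1, t[3]))
  theta <- acos(ct) * d
  psi <- if (abs(ct) > 1 - 1e-12) 0 else atan2(t[1], -t[2]) * d
  c(theta = theta, psi = psi)
}

#' Wrap angles to (-180, 180]
#' @param a angles in degrees.
#' @return wrapped angles.
#' @export
wrap180 <- function(a) {
  w <- (a + 180) %% 360 - 180
  w[w == -180] <- 180
  w
}
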