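# Rotation algebra shared by tensor co-alignment, pose decomposition and the
# conformer grid search. All angles at the interface are in degrees.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Rotation matrix about an arbitrary axis
#'
#' Rodrigues construction of the proper rotation by `angle` degrees about the
#' unit vector `axis`.
#'
#' @param axis numeric length-3 axis (normalized internally; must be nonzero).
#' @param angle rotation angle in degrees.
#' @return 3x3 proper rotation matrix.
#' @export
rotation_about_axis <- function(axis, angle) {
  n <- sqrt(sum(axis^2))
  if (n < 1e-12) stop("rotation axis must be nonzero")
  u <- axis / n
  th <- deg2rad(angle)
  K <- matrix(c(0, u[3], -u[2],
                -u[3], 0, u[1],
                u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Rotation matrices about the Cartesian axes
#'
#' @param rx,ry,rz angles in degrees about x, y and z.
#' @return 3x3 rotation `Rx %*% Ry %*% Rz` (z applied first).
#' @export
rotation_xyz <- function(rx = 0, ry = 0, rz = 0) {
  rotation_about_axis(c(1, 0, 0), rx) %*%
    rotation_about_axis(c(0, 1, 0), ry) %*%
    rotation_about_axis(c(0, 0, 1), rz)
}

#' Axis-angle extraction from a rotation matrix
#'
#' Extracts the single equivalent rotation axis and angle from a proper
#' rotation, using the antisymmetric part away from 180 degrees and the
#' symmetric-part eigenvector at (or very near) 180 degrees. The axis sign is
#' chosen so the angle is non-negative; the identity reports the +z axis with
#' angle 0. The axis is also reported in spherical coordinates: `phi` is the
#' polar angle from +z and `psi` the azimuth from +x, both in degrees.
#'
#' @param rotation 3x3 proper rotation matrix.
#' @return list with `axis` (unit 3-vector), `angle` (degrees, in [0, 180]),
#'   `phi`, `psi` (degrees).
#' @export
axis_angle <- function(rotation) {
  R <- rotation
  stopifnot(is.matrix(R), all(dim(R) == c(3, 3)))
  if (abs(det(R) - 1) > 1e-6)
    stop("axis_angle requires a proper rotation (det = +1)")
  tr <- sum(diag(R))
  cth <- max(-1, min(1, (tr - 1) / 2))
  angle <- acos(cth)
  w <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) / 2
  sn <- sqrt(sum(w^2))
  if (angle < 1e-9) {
    axis <- c(0, 0, 1)
    angle <- 0
  } else if (pi - angle > 1e-4) {
    axis <- w / sn
  } else {
    # near 180 deg: axis from the eigenvector of (R + t(R))/2 with eigenvalue 1
    S <- (R + t(R)) / 2
    e <- eigen(S, symmetric = TRUE)
    axis <- e$vectors[, which.max(e$values)]
    # fix sign from the (possibly tiny) antisymmetric part
    if (sn > 1e-12 && sum(axis * w) < 0) axis <- -axis
    # canonical sign at exactly 180 deg: first nonzero component positive
    if (sn <= 1e-12) {
      k <- which(abs(axis) > 1e-8)[1]
      if (axis[k] < 0) axis <- -axis
    }
  }
  list(axis = axis,
       angle = rad2deg(angle),
       phi = rad2deg(acos(max(-1, min(1, axis[3])))),
       psi = rad2deg(atan2(axis[2], axis[1])))
}

#' Factor a rotation into rotations about three given orthogonal axes
#'
#' Finds angles (a1, a2, a3), in degrees, such that
#' `R = R(axis1, a1) %*% R(axis2, a2) %*% R(axis3, a3)`
#' (the axis3 rotation is applied first). The axes need not form a
#' right-handed triple; handedness is absorbed into the angle signs.
#'
#' @param rotation 3x3 proper rotation.
#' @param axes 3x3 matrix whose columns are the three (unit, mutually
#'   orthogonal) rotation axes, in application order left to right.
#' @return numeric length-3 vector of angles in degrees; attribute
#'   `"gimbal"` is TRUE when the middle angle is within 0.1 degree of +/-90,
#'   in which case the first and third angles are not separable (their sum is
#'   reported in the first slot, 0 in the third).
#' @export
factor_rotation <- function(rotation, axes) {
  B <- axes
  stopifnot(all(dim(B) == c(3, 3)))
  if (max(abs(crossprod(B) - diag(3))) > 1e-8)
    stop("axes must be orthonormal")
  s3 <- 1
  if (det(B) < 0) {            # flip third axis into a right-handed basis
    B[, 3] <- -B[, 3]
    s3 <- -1
  }
  Rp <- t(B) %*% rotation %*% B  # rotation expressed in the axes basis
  # Rp = Rx(a1) Ry(a2) Rz(a3):
  #   Rp[1,3] = sin a2 ; Rp[2,3] = -sin a1 cos a2 ; Rp[3,3] = cos a1 cos a2
  #   Rp[1,2] = -cos a2 sin a3 ; Rp[1,1] = cos a2 cos a3
  sb <- max(-1, min(1, Rp[1, 3]))
  a2 <- asin(sb)
  gimbal <- abs(abs(a2) - pi / 2) < deg2rad(0.1)
  if (!gimbal) {
    a1 <- atan2(-Rp[2, 3], Rp[3, 3])
    a3 <- atan2(-Rp[1, 2], Rp[1, 1])
  } else {
    # only a1 +/- a3 is determined; report the sum about axis1
    a1 <- atan2(Rp[2, 1], Rp[2, 2])
    if (a2 < 0) a1 <- -a1
    a3 <- 0
    warning("rotation factorization near gimbal lock; ",
            "first and third angles reported as their sum")
  }
  out <- c(rad2deg(a1), rad2deg(a2), s3 * rad2deg(a3))
  attr(out, "gimbal") <- gimbal
  out
}
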