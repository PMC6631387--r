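#' Spatial (6-D) vector algebra
#'
#' All 6-vectors in this package are ordered linear block first, then
#' angular: a twist is \code{(v, omega)}, a wrench \code{(f, m)}, a spatial
#' acceleration \code{(a_lin, a_ang)}.  A frame is written as a pair
#' (rotation, origin): the rotation maps child-frame coordinates into
#' parent-frame coordinates and the origin is the position of the child
#' frame origin expressed in the parent frame.
#'
#' @name spatial-algebra
#' @keywords internal
NULL

#' Skew-symmetric (cross-product) matrix
#'
#' Returns the 3x3 antisymmetric matrix \code{S(x)} such that
#' \code{S(x) \%*\% y == x x y} (vector cross product) for every \code{y}.
#'
#' @param x numeric 3-vector.
#' @return 3x3 antisymmetric matrix.
#' @export
#' @examples
#' skew(c(1, 0, 0)) %*% c(0, 1, 0)   # the z axis
skew <- function(x) {
  stopifnot(length(x) == 3L, all(is.finite(x)))
  matrix(c(0, x[3], -x[2],
           -x[3], 0, x[1],
           x[2], -x[1], 0), 3L, 3L)
}

#' Rotation about a unit axis
#'
#' Rodrigues' formula for the rotation of angle \code{theta} (radians)
#' about the unit 3-vector \code{axis}.
#'
#' @param axis unit 3-vector.
#' @param theta angle in radians.
#' @return 3x3 rotation matrix.
#' @export
rot_axis_angle <- function(axis, theta) {
  a <- axis / sqrt(sum(axis^2))
  K <- skew(a)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

## Elementary rotations used by the RPY (extrinsic x-y-z) convention.
rot_x <- function(t) rot_axis_angle(c(1, 0, 0), t)
rot_y <- function(t) rot_axis_angle(c(0, 1, 0), t)
rot_z <- function(t) rot_axis_angle(c(0, 0, 1), t)

#' Rotation from URDF roll-pitch-yaw angles
#'
#' Extrinsic x-y-z convention: \code{R = Rz(yaw) Ry(pitch) Rx(roll)}.
#'
#' @param rpy numeric 3-vector (roll, pitch, yaw) in radians.
#' @return 3x3 rotation matrix.
#' @export
rot_rpy <- function(rpy) rot_z(rpy[3]) %*% rot_y(rpy[2]) %*% rot_x(rpy[1])

#' Intrinsic Z-Y-X Euler angles of a rotation
#'
#' Inverse of the yaw-pitch-roll factorization; used as the rotation-error
#' parameterization of the pairwise inverse kinematics objective.
#'
#' @param R 3x3 rotation matrix.
#' @return numeric 3-vector (yaw, pitch, roll) in radians.
#' @export
euler_zyx <- function(R) {
  pitch <- asin(max(-1, min(1, -R[3, 1])))
  if (abs(R[3, 1]) < 1 - 1e-12) {
    yaw <- atan2(R[2, 1], R[1, 1])
    roll <- atan2(R[3, 2], R[3, 3])
  } else {
    # gimbal lock: spread the residual freedom into yaw
    yaw <- atan2(-R[1, 2], R[2, 2])
    roll <- 0
  }
  c(yaw, pitch, roll)
}

#' Validate a rotation matrix
#'
#' @param R 3x3 matrix.
#' @param tol orthonormality tolerance.
#' @return \code{R}, invisibly; errors if not in SO(3).
#' @export
check_rotation <- function(R, tol = 1e-10) {
  stopifnot(is.matrix(R), all(dim(R) == c(3L, 3L)))
  if (max(abs(crossprod(R) - diag(3))) > tol)
    stop("matrix is not orthonormal within tolerance ", tol)
  if (abs(det(R) - 1) > tol)
    stop("matrix determinant is not +1 within tolerance ", tol)
  invisible(R)
}

#' Spatial transform (frame pose)
#'
#' A rigid transform holding the rotation of the child frame expressed in
#' the parent frame and the position of the child origin in the parent
#' frame: a point \code{p} in child coordinates maps to
#' \code{R \%*\% p + origin} in parent coordinates.
#'
#' @param R 3x3 rotation (child coordinates to parent coordinates).
#' @param origin position of the child origin in the parent frame (3-vector,
#'   metres).
#' @return object of class \code{"spatial_transform"}.
#' @export
spatial_transform <- function(R = diag(3), origin = c(0, 0, 0)) {
  check_rotation(R)
  stopifnot(length(origin) == 3L, all(is.finite(origin)))
  structure(list(R = R, origin = as.numeric(origin)),
            class = "spatial_transform")
}

#' @export
print.spatial_transform <- function(x, ...) {
  cat("spatial transform\n  origin:", format(x$origin, digits = 4), "\n")
  cat("  rotation:\n")
  print(round(x$R, 6))
  invisible(x)
}

#' Compose two spatial transforms
#'
#' \code{T_ac = compose_transform(T_ab, T_bc)}.
#'
#' @param T1,T2 spatial transforms.
#' @return composed spatial transform.
#' @export
compose_transform <- function(T1, T2) {
  spatial_transform(T1$R %*% T2$R, as.numeric(T1$R %*% T2$origin) + T1$origin)
}

#' Invert a spatial transform
#' @param T spatial transform.
#' @return the inverse transform.
#' @export
invert_transform <- function(T) {
  spatial_transform(t(T$R), as.numeric(-t(T$R) %*% T$origin))
}

#' Adjoint transform for motion vectors
#'
#' The 6x6 operator mapping a twist (or spatial acceleration) expressed in
#' the child frame to the parent frame.  With the (linear; angular) ordering
#' and \code{T = (R, o)} it is \code{[[R, S(o) R], [0, R]]}.  Set
#' \code{rotation_only = TRUE} for the orientation-only form
#' \code{[[R, 0], [0, R]]}, which is the pure change of coordinates used for
#' proper sensor accelerations between frames sharing an origin.
#'
#' @param T spatial transform.
#' @param rotation_only logical; drop the origin-shift block.
#' @return 6x6 matrix.
#' @export
motion_adjoint <- function(T, rotation_only = FALSE) {
  X <- matrix(0, 6L, 6L)
  X[1:3, 1:3] <- T$R
  X[4:6, 4:6] <- T$R
  if (!rotation_only) X[1:3, 4:6] <- skew(T$origin) %*% T$R
  X
}

#' Adjoint transform for force vectors
#'
#' Dual of \code{\link{motion_adjoint}} under power invariance
#' (\code{t(X_star) == solve(X)}): maps a wrench expressed in the child
#' frame to the parent frame, \code{[[R, 0], [S(o) R, R]]}.
#'
#' @inheritParams motion_adjoint
#' @return 6x6 matrix.
#' @export
force_adjoint <- function(T, rotation_only = FALSE) {
  X <- matrix(0, 6L, 6L)
  X[1:3, 1:3] <- T$R
  X[4:6, 4:6] <- T$R
  if (!rotation_only) X[4:6, 1:3] <- skew(T$origin) %*% T$R
  X
}

#' Spatial cross product for motion vectors
#'
#' \code{crm(v)} is the 6x6 matrix of \code{v x} acting on motion vectors:
#' \code{[[S(w), S(vl)], [0, S(w)]]} for \code{v = (vl, w)}.
#'
#' @param v 6-vector (linear; angular).
#' @return 6x6 matrix.
#' @export
cross_motion <- function(v) {
  X <- matrix(0, 6L, 6L)
  Sw <- skew(v[4:6])
  X[1:3, 1:3] <- Sw
  X[4:6, 4:6] <- Sw
  X[1:3, 4:6] <- skew(v[1:3])
  X
}

#' Dual spatial cross product for force vectors
#'
#' \code{cross_force(v) == -t(cross_motion(v))}; acts on wrenches.
#'
#' @param v 6-vector (linear; angular).
#' @return 6x6 matrix.
#' @export
cross_force <- function(v) -t(cross_motion(v))

#' Spatial inertia of a rigid link
#'
#' Mass, first moment of mass (mass times centre of mass position) and
#' rotational inertia, all at the link frame origin in link coordinates.
#'
#' @param mass scalar mass in kg, positive.
#' @param com centre of mass position in the link frame (3-vector, m).
#' @param inertia 3x3 symmetric positive-definite rotational inertia at the
#'   link origin (kg m^2).  NOTE: at the origin, not at the COM.
#' @return object of class \code{"spatial_inertia"}.
#' @export
spatial_inertia <- function(mass, com = c(0, 0, 0), inertia = diag(3) * 1e-3) {
  stopifnot(is.numeric(mass), length(mass) == 1L, mass > 0,
            length(com) == 3L, all(dim(inertia) == c(3L, 3L)))
  if (max(abs(inertia - t(inertia))) > 1e-9)
    stop("rotational inertia must be symmetric")
  if (any(eigen(inertia, symmetric = TRUE, only.values = TRUE)$values <= 0))
    stop("rotational inertia must be positive definite")
  structure(list(mass = mass, h = mass * as.numeric(com), inertia = inertia),
            class = "spatial_inertia")
}

#' Assemble the 6x6 spatial inertia matrix
#'
#' \code{[[m I, t(S(h))], [S(h), I_o]]} in the (linear; angular) ordering,
#' with \code{h} the first moment of mass.
#'
#' @param M a \code{spatial_inertia}.
#' @return 6x6 symmetric positive-definite matrix.
#' @export
inertia_matrix <- function(M) {
  X <- matrix(0, 6L, 6L)
  X[1:3, 1:3] <- diag(3) * M$mass
  Sh <- skew(M$h)
  X[1:3, 4:6] <- t(Sh)
  X[4:6, 1:3] <- Sh
  X[4:6, 4:6] <- M$inertia
  X
}

## Rotational inertia at the COM -> at the link origin (parallel axis).
inertia_at_origin <- function(I_com, mass, com) {
  S <- skew(com)
  I_com - mass * (S %*% S)
}

#' Quaternion to rotation matrix
#'
#' Convention \code{(w, x, y, z)}, unit norm enforced by normalization.
#'
#' @param q numeric 4-vector.
#' @return 3x3 rotation matrix.
#' @export
quat_to_rot <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3L, 3L)
}

#' Rotation matrix to quaternion
#'
#' Inverse of \code{\link{quat_to_rot}}; returns the hemisphere with
#' non-negative scalar part.
#'
#' @param R 3x3 rotation matrix.
#' @return numeric 4-vector \code{(w, x, y, z)}.
#' @export
rot_to_quat <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s,
           (R[1, 3] - R[3, 1]) / s, (R[2, 1] - R[1, 2]) / s)
  } else {
    i <- which.max(c(R[1, 1], R[2, 2], R[3, 3]))
    if (i == 1L) {
      s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
      q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s,
             (R[1, 2] + R[2, 1]) / s, (R[1, 3] + R[3, 1]) / s)
    } else if (i == 2L) {
      s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
      q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s,
             0.25 * s, (R[2, 3] + R[3, 2]) / s)
    } else {
      s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
      q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
             (R[2, 3] + R[3, 2]) / s, 0.25 * s)
    }
  }
  if (q[1] < 0) q <- -q
  q
}

#' Default gravity vector
#'
#' Inertial-frame gravitational acceleration, z axis pointing up:
#' \code{c(0, 0, -9.81)} m/s^2.
#'
#' @return numeric 3-vector.
#' @export
default_gravity <- function() c(0, 0, -9.81)
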