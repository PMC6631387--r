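#' System state of a floating-base model
#'
#' Base pose, joint positions, and optionally the system velocity and
#' acceleration.  The base velocity is the mixed representation
#' \code{(d/dt base position, base angular velocity)}, both expressed in
#' inertial coordinates; the base acceleration is its plain time
#' derivative.
#'
#' @param base_R base orientation, inertial from base (3x3 rotation).
#' @param base_pos base origin in the inertial frame (m).
#' @param s joint positions (rad or m), length \code{n_joints(model)}.
#' @param base_vel 6-vector \code{(linear, angular)} in inertial
#'   coordinates (m/s, rad/s).
#' @param s_dot joint velocities.
#' @param base_acc 6-vector \code{(linear, angular)} inertial (m/s^2,
#'   rad/s^2).
#' @param s_ddot joint accelerations.
#' @return object of class \code{"system_state"}.
#' @export
system_state <- function(base_R = diag(3), base_pos = c(0, 0, 0),
                         s = numeric(0),
                         base_vel = numeric(6), s_dot = 0 * s,
                         base_acc = numeric(6), s_ddot = 0 * s) {
  check_rotation(base_R)
  stopifnot(length(base_pos) == 3L, length(base_vel) == 6L,
            length(base_acc) == 6L,
            length(s_dot) == length(s), length(s_ddot) == length(s))
  structure(list(base_R = base_R, base_pos = as.numeric(base_pos),
                 s = as.numeric(s), base_vel = as.numeric(base_vel),
                 s_dot = as.numeric(s_dot), base_acc = as.numeric(base_acc),
                 s_ddot = as.numeric(s_ddot)),
            class = "system_state")
}

#' Forward position/velocity/acceleration kinematics for every link
#'
#' Propagates the base state through the joint recursion and returns, per
#' link, the pose, inertial-frame angular velocity/acceleration, origin
#' velocity/acceleration, the body-frame angular velocity, and the proper
#' sensor acceleration \code{alpha_g} (linear part
#' \code{t(R) (pddot - g)}, angular part \code{t(R) omegadot}, both in
#' link coordinates).
#'
#' @param model a \code{multibody_model}.
#' @param state a \code{system_state} with dimensions matching the model.
#' @param gravity inertial gravity vector (default \code{c(0, 0, -9.81)}).
#' @return list with per-link lists \code{R}, \code{joint_T} and matrices
#'   (one column per link) \code{p}, \code{omega_I}, \code{pdot},
#'   \code{omegadot_I}, \code{pddot}, \code{omega_body}, \code{alpha_g}.
#' @export
link_kinematics <- function(model, state, gravity = default_gravity()) {
  nb <- n_links(model)
  if (length(state$s) != n_joints(model))
    stop("state has ", length(state$s), " joint positions, model needs ",
         n_joints(model))
  R <- vector("list", nb)
  joint_T <- vector("list", nb)   # [[i]]: child-i frame in parent frame
  p <- pdot <- pddot <- omega_I <- omegadot_I <- matrix(0, 3L, nb)
  R[[1]] <- state$base_R
  p[, 1] <- state$base_pos
  pdot[, 1] <- state$base_vel[1:3]
  omega_I[, 1] <- state$base_vel[4:6]
  pddot[, 1] <- state$base_acc[1:3]
  omegadot_I[, 1] <- state$base_acc[4:6]
  for (i in seq_len(nb)[-1]) {
    jt <- model$joints[[i - 1L]]
    la <- jt$parent
    sj <- state$s[i - 1L]; sdj <- state$s_dot[i - 1L]; sddj <- state$s_ddot[i - 1L]
    T <- joint_transform(jt, sj)
    joint_T[[i]] <- T
    Rl <- R[[la]]
    R[[i]] <- Rl %*% T$R
    r <- as.numeric(Rl %*% T$origin)        # child origin offset, inertial
    p[, i] <- p[, la] + r
    if (jt$type == "prismatic") {
      odot <- as.numeric(jt$R_off %*% (jt$axis * sdj))    # in parent coords
      oddot <- as.numeric(jt$R_off %*% (jt$axis * sddj))
      a_w <- numeric(3)
    } else {
      odot <- oddot <- numeric(3)
      a_w <- as.numeric(R[[i]] %*% jt$axis)               # axis, inertial
    }
    odot_I <- as.numeric(Rl %*% odot)
    w_la <- omega_I[, la]
    omega_I[, i] <- w_la + a_w * sdj
    pdot[, i] <- pdot[, la] + cross3(w_la, r) + odot_I
    omegadot_I[, i] <- omegadot_I[, la] + a_w * sddj +
      cross3(omega_I[, i], a_w) * sdj
    pddot[, i] <- pddot[, la] + cross3(omegadot_I[, la], r) +
      cross3(w_la, cross3(w_la, r)) + 2 * cross3(w_la, odot_I) +
      as.numeric(Rl %*% oddot)
  }
  omega_body <- matrix(0, 3L, nb)
  alpha_g <- matrix(0, 6L, nb)
  for (i in seq_len(nb)) {
    Rt <- t(R[[i]])
    omega_body[, i] <- as.numeric(Rt %*% omega_I[, i])
    alpha_g[, i] <- c(as.numeric(Rt %*% (pddot[, i] - gravity)),
                      as.numeric(Rt %*% omegadot_I[, i]))
  }
  list(R = R, joint_T = joint_T, p = p, pdot = pdot, pddot = pddot,
       omega_I = omega_I, omegadot_I = omegadot_I,
       omega_body = omega_body, alpha_g = alpha_g)
}

cross3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                           a[3] * b[1] - a[1] * b[3],
                           a[1] * b[2] - a[2] * b[1])

## Newton-Euler velocity-product bias at link i, body coordinates:
## (0; w) x* M (0; w).
ne_bias <- function(inertia, omega_body) {
  Mv <- inertia_matrix(inertia) %*% c(0, 0, 0, omega_body)
  as.numeric(cross_force(c(0, 0, 0, omega_body)) %*% Mv)
}

#' Recursive Newton-Euler inverse dynamics (ground-truth oracle)
#'
#' Given a complete state (including base acceleration) and the external
#' wrench applied to every link (link coordinates), runs the backward
#' force recursion on the proper-sensor-acceleration balance
#' \code{M alpha_g + (0; w) x* M (0; w) = f_ext + f_joint - sum(X* f_child)}
#' and returns the joint torques, the joint wrenches (wrench transmitted
#' from the parent to the child, child coordinates) and the base residual:
#' the extra external wrench the base would need for the motion to be
#' dynamically consistent.  The residual is zero for physically consistent
#' trajectories (e.g. free fall with no applied wrench).
#'
#' @param model a \code{multibody_model}.
#' @param state a \code{system_state} with velocities and accelerations.
#' @param f_ext 6 x \code{n_links} matrix of external wrenches in link
#'   coordinates (default all zero).
#' @param gravity inertial gravity vector.
#' @param kin optional precomputed \code{\link{link_kinematics}}.
#' @return list with \code{tau} (n-vector), \code{joint_wrench}
#'   (6 x n matrix), \code{base_residual} (6-vector, base coordinates) and
#'   the \code{kin} used.
#' @export
rnea_oracle <- function(model, state, f_ext = NULL,
                        gravity = default_gravity(), kin = NULL) {
  nb <- n_links(model)
  n <- n_joints(model)
  if (is.null(f_ext)) f_ext <- matrix(0, 6L, nb)
  if (!all(dim(f_ext) == c(6L, nb)))
    stop("f_ext must be a 6 x ", nb, " matrix")
  if (is.null(kin)) kin <- link_kinematics(model, state, gravity)
  fj <- matrix(0, 6L, nb)   # column i: net wrench link i passes to its parent
  for (i in rev(seq_len(nb))) {
    w <- as.numeric(inertia_matrix(model$links[[i]]$inertia) %*% kin$alpha_g[, i]) +
      ne_bias(model$links[[i]]$inertia, kin$omega_body[, i]) - f_ext[, i]
    for (c in model$children[[i]])
      w <- w + as.numeric(force_adjoint(kin$joint_T[[c]]) %*% fj[, c])
    fj[, i] <- w
  }
  tau <- numeric(n)
  for (j in seq_len(n))
    tau[j] <- sum(joint_motion_subspace(model$joints[[j]]) * fj[, j + 1L])
  list(tau = tau,
       joint_wrench = if (n > 0L) fj[, -1L, drop = FALSE] else matrix(0, 6L, 0L),
       base_residual = fj[, 1L], kin = kin)
}

## Rotation-only force adjoint from body to inertial orientation.
rot_force6 <- function(R) {
  X <- matrix(0, 6L, 6L)
  X[1:3, 1:3] <- R
  X[4:6, 4:6] <- R
  X
}

#' Mass matrix and bias vector of the floating-base model
#'
#' Assembles the \code{(6+n) x (6+n)} generalized mass matrix \code{M(q)}
#' by the composite-rigid-body algorithm and the bias vector
#' \code{h(q, nu)} (Coriolis, centrifugal and gravity terms) by a
#' zero-acceleration Newton-Euler pass, in the mixed base coordinates of
#' \code{\link{system_state}}.  The system then satisfies
#' \code{M(q) nudot + h(q, nu) = B tau + sum(t(J_k) w_k)} with the contact
#' Jacobians of \code{\link{contact_jacobian}} and wrenches expressed in
#' inertial orientation at the link origins.
#'
#' @inheritParams rnea_oracle
#' @return list with \code{M} (\code{(6+n) x (6+n)} symmetric positive
#'   definite) and \code{h} (\code{(6+n)}-vector).
#' @export
mass_matrix_and_bias <- function(model, state, gravity = default_gravity()) {
  nb <- n_links(model)
  n <- n_joints(model)
  kin <- link_kinematics(model, state, gravity)
  # composite inertias, body coordinates
  Mc <- lapply(model$links, function(l) inertia_matrix(l$inertia))
  for (i in rev(seq_len(nb))) {
    for (c in model$children[[i]]) {
      Xci <- motion_adjoint(invert_transform(kin$joint_T[[c]]))  # i -> c
      Mc[[i]] <- Mc[[i]] + t(Xci) %*% Mc[[c]] %*% Xci
    }
  }
  M <- matrix(0, 6L + n, 6L + n)
  Xb <- matrix(0, 6L, 6L)   # base body coords -> mixed inertial base coords
  Xb[1:3, 1:3] <- t(kin$R[[1]]); Xb[4:6, 4:6] <- t(kin$R[[1]])
  M[1:6, 1:6] <- t(Xb) %*% Mc[[1]] %*% Xb
  for (j in seq_len(n)) {
    i <- j + 1L
    Fi <- as.numeric(Mc[[i]] %*% joint_motion_subspace(model$joints[[j]]))
    M[6L + j, 6L + j] <- sum(joint_motion_subspace(model$joints[[j]]) * Fi)
    k <- i
    while (!is.na(model$parent[k])) {
      la <- model$parent[k]
      Fi <- as.numeric(t(motion_adjoint(invert_transform(kin$joint_T[[k]]))) %*% Fi)
      if (la == 1L) {
        M[1:6, 6L + j] <- as.numeric(t(Xb) %*% Fi)
        M[6L + j, 1:6] <- M[1:6, 6L + j]
      } else {
        Sk <- joint_motion_subspace(model$joints[[la - 1L]])
        M[6L + la - 1L, 6L + j] <- sum(Sk * Fi)
        M[6L + j, 6L + la - 1L] <- M[6L + la - 1L, 6L + j]
      }
      k <- la
    }
  }
  # bias via zero-acceleration inverse dynamics
  st0 <- state
  st0$base_acc <- numeric(6)
  st0$s_ddot <- numeric(n)
  id0 <- rnea_oracle(model, st0, gravity = gravity)
  h <- c(as.numeric(rot_force6(kin$R[[1]]) %*% id0$base_residual), id0$tau)
  list(M = M, h = h)
}

#' Mass matrix by unit-acceleration inverse-dynamics columns
#'
#' Independent assembly of \code{M(q)}: column k is the generalized force
#' of a pure unit acceleration in coordinate k with zero velocity and zero
#' gravity.  Used to cross-check the composite-rigid-body assembly.
#'
#' @inheritParams rnea_oracle
#' @return \code{(6+n) x (6+n)} matrix.
#' @export
mass_matrix_rnea <- function(model, state) {
  n <- n_joints(model)
  m <- 6L + n
  M <- matrix(0, m, m)
  base_R <- state$base_R
  for (k in seq_len(m)) {
    st <- system_state(base_R, state$base_pos, state$s)
    if (k <= 6L) st$base_acc[k] <- 1 else st$s_ddot[k - 6L] <- 1
    id <- rnea_oracle(model, st, gravity = c(0, 0, 0))
    M[, k] <- c(as.numeric(rot_force6(base_R) %*% id$base_residual), id$tau)
  }
  M
}
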