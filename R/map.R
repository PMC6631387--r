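#' Serialization of the stacked estimation vector d
#'
#' The unknowns of the stochastic dynamics system are stacked per link and
#' per joint: for every link (topological order, base first) the 6-D
#' proper sensor acceleration \code{alpha_g} then the 6-D external wrench
#' \code{fx}; then for every joint the 6-D joint wrench, then every joint
#' acceleration scalar.  Total length \code{12 N_B + 7 n}.
#'
#' @param model a \code{multibody_model}.
#' @param what one of \code{"alpha"}, \code{"fx"} (link quantities),
#'   \code{"fjoint"}, \code{"sddot"} (joint quantities).
#' @param i link index (for \code{alpha}/\code{fx}) or joint index.
#' @return integer vector of positions in \code{d}.
#' @export
d_index <- function(model, what = c("alpha", "fx", "fjoint", "sddot"), i) {
  what <- match.arg(what)
  nb <- n_links(model)
  n <- n_joints(model)
  switch(what,
         alpha = { stopifnot(i >= 1L, i <= nb); (i - 1L) * 12L + 1:6 },
         fx = { stopifnot(i >= 1L, i <= nb); (i - 1L) * 12L + 7:12 },
         fjoint = { stopifnot(i >= 1L, i <= n); 12L * nb + (i - 1L) * 6L + 1:6 },
         sddot = { stopifnot(i >= 1L, i <= n); 12L * nb + 6L * n + i })
}

#' @rdname d_index
#' @export
d_length <- function(model) 12L * n_links(model) + 7L * n_joints(model)

#' Convert between proper sensor and proper body acceleration
#'
#' The proper sensor acceleration \code{alpha_g} (what an ideal
#' accelerometer/gyro pair reads: link-frame coordinates of the
#' gravity-compensated origin acceleration and angular acceleration)
#' differs from the proper body acceleration \code{a_g} (the body-frame
#' derivative of the link spatial velocity minus gravity) by the
#' velocity-product term \code{((v_lin x omega); 0)} with both vectors in
#' link coordinates.
#'
#' @param alpha_g proper sensor acceleration (6-vector, link coords).
#' @param v_lin link origin linear velocity in link coordinates (m/s).
#' @param omega link angular velocity in link coordinates (rad/s).
#' @return the converted 6-vector.
#' @export
proper_body_from_sensor <- function(alpha_g, v_lin, omega) {
  alpha_g - c(cross3(v_lin, omega), 0, 0, 0)
}

#' @rdname proper_body_from_sensor
#' @param a_g proper body acceleration (6-vector, link coords).
#' @export
proper_sensor_from_body <- function(a_g, v_lin, omega) {
  a_g + c(cross3(v_lin, omega), 0, 0, 0)
}

#' Body angular velocities and joint transforms from the configuration
#'
#' The velocity-product terms of the dynamics system need only the joint
#' positions/rates and the base angular velocity (no base pose and no
#' linear velocities).  Returns, per link, the child-in-parent joint
#' transform, the body-frame angular velocity, and the bias of the
#' acceleration-propagation equation.
#'
#' @param model a \code{multibody_model}.
#' @param s,s_dot joint positions and velocities.
#' @param base_omega base angular velocity in base coordinates (rad/s).
#' @return list with \code{joint_T}, \code{omega_body} (3 x N_B) and
#'   \code{acc_bias} (6 x N_B, base column zero).
#' @keywords internal
body_kinematics <- function(model, s, s_dot, base_omega = c(0, 0, 0)) {
  nb <- n_links(model)
  joint_T <- vector("list", nb)
  omega_body <- matrix(0, 3L, nb)
  acc_bias <- matrix(0, 6L, nb)
  omega_body[, 1L] <- base_omega
  for (i in seq_len(nb)[-1L]) {
    jt <- model$joints[[i - 1L]]
    T <- joint_transform(jt, s[i - 1L])
    joint_T[[i]] <- T
    E <- t(T$R)                       # parent coords -> child coords
    w <- as.numeric(E %*% omega_body[, jt$parent])
    S <- joint_motion_subspace(jt)
    omega_body[, i] <- w + S[4:6] * s_dot[i - 1L]
    r <- as.numeric(E %*% T$origin)   # child-to-parent offset, child coords
    acc_bias[, i] <- c(cross3(w, cross3(w, r)) +
                         2 * cross3(w, S[1:3] * s_dot[i - 1L]),
                       cross3(omega_body[, i], S[4:6] * s_dot[i - 1L]))
  }
  list(joint_T = joint_T, omega_body = omega_body, acc_bias = acc_bias)
}

#' Assemble the stacked dynamics system D d + b_D = 0
#'
#' Builds the sparse matrix form of the acceleration-propagation and
#' Newton-Euler link balances in the \code{\link{d_index}} serialization:
#' per link, rows 1-6 propagate the proper sensor acceleration from the
#' parent through the joint, rows 7-12 balance the link wrenches.  The
#' base link has no parent: its acceleration rows pin \code{alpha_base}
#' to the known base proper sensor acceleration \code{base_alpha}
#' (supplied with the base kinematics stream; its velocity-dependent part
#' is the classic alpha-bar correction), and its balance rows carry no
#' parent joint wrench.
#'
#' @param model a \code{multibody_model}.
#' @param s,s_dot joint positions and velocities.
#' @param base_omega base angular velocity, base coordinates (rad/s).
#' @param base_alpha known base proper sensor acceleration (6-vector).
#' @param kin0 optional precomputed \code{\link{body_kinematics}}.
#' @return list with sparse \code{D} (\code{12 N_B x d}), \code{b}
#'   (\code{12 N_B}) and \code{kin0}.
#' @export
build_dynamics_system <- function(model, s, s_dot, base_omega, base_alpha,
                                  kin0 = NULL) {
  nb <- n_links(model)
  if (length(s) != n_joints(model) || length(s_dot) != n_joints(model))
    stop("joint vectors must have length ", n_joints(model))
  if (length(base_alpha) != 6L) stop("base_alpha must be a 6-vector")
  if (is.null(kin0)) kin0 <- body_kinematics(model, s, s_dot, base_omega)
  trip_i <- trip_j <- trip_x <- vector("list", 6L * nb)
  b <- numeric(12L * nb)
  k <- 0L
  add <- function(rows, cols, block) {
    k <<- k + 1L
    trip_i[[k]] <<- rep(rows, times = length(cols))
    trip_j[[k]] <<- rep(cols, each = length(rows))
    trip_x[[k]] <<- as.numeric(block)
  }
  for (i in seq_len(nb)) {
    acc_rows <- (i - 1L) * 12L + 1:6
    ne_rows <- (i - 1L) * 12L + 7:12
    add(acc_rows, d_index(model, "alpha", i), -diag(6))
    if (i == 1L) {
      b[acc_rows] <- base_alpha
    } else {
      jt <- model$joints[[i - 1L]]
      Xlam <- motion_adjoint(invert_transform(kin0$joint_T[[i]]))
      add(acc_rows, d_index(model, "alpha", jt$parent), Xlam)
      add(acc_rows, d_index(model, "sddot", i - 1L),
          matrix(joint_motion_subspace(jt), 6L, 1L))
      b[acc_rows] <- kin0$acc_bias[, i]
    }
    add(ne_rows, d_index(model, "alpha", i),
        inertia_matrix(model$links[[i]]$inertia))
    add(ne_rows, d_index(model, "fx", i), -diag(6))
    if (i > 1L)
      add(ne_rows, d_index(model, "fjoint", i - 1L), -diag(6))
    for (c in model$children[[i]])
      add(ne_rows, d_index(model, "fjoint", c - 1L),
          force_adjoint(kin0$joint_T[[c]]))
    b[ne_rows] <- ne_bias(model$links[[i]]$inertia, kin0$omega_body[, i])
  }
  D <- Matrix::sparseMatrix(i = unlist(trip_i), j = unlist(trip_j),
                            x = unlist(trip_x),
                            dims = c(12L * nb, d_length(model)))
  list(D = D, b = b, kin0 = kin0)
}

#' Sensor layout: which channels measure which entries of d
#'
#' Describes the distributed sensor set.  Channel kinds:
#' \describe{
#'   \item{imu}{3-axis accelerometer rigidly mounted on a link; measures
#'     the linear part of the proper sensor acceleration at the sensor
#'     frame (3 rows).  With \code{imu_full = TRUE} the angular
#'     acceleration rows are included too (6 rows) for fully instrumented
#'     synthetic setups; by default the angular acceleration is not a
#'     measurement and is constrained only through the model rows.}
#'   \item{ft}{6-axis force/torque sensor rigidly connected to a contact
#'     link; measures the link external wrench expressed in the sensor
#'     frame (6 rows).}
#'   \item{null_wrench}{zero-valued pseudo-measurement declaring a link
#'     free of external contact (6 rows); without these, external wrenches
#'     on uninstrumented links are not separable from joint wrenches.}
#'   \item{jacc}{a differentiated joint-position channel measuring one
#'     joint acceleration (1 row).}
#' }
#'
#' @param model a \code{multibody_model}.
#' @param imu_links links carrying an IMU (indices); default all links.
#' @param imu_transforms optional list (parallel to \code{imu_links}) of
#'   \code{spatial_transform}s of each sensor frame in its link frame.
#' @param imu_full logical; include angular-acceleration rows.
#' @param ft_links links carrying a force/torque sensor (e.g. the feet).
#' @param ft_transforms optional list of sensor-in-link transforms.
#' @param null_wrench_links links declared contact-free; default all links
#'   except \code{ft_links} and the base (whose wrench stays unconstrained
#'   to absorb un-modelled support) when \code{include_base_null = FALSE}.
#' @param include_base_null logical; add a null-wrench channel on the base.
#' @param jacc_joints joints with an acceleration channel; default all.
#' @param var_imu,var_ft,var_jacc,var_null per-channel measurement
#'   variances (diagonal entries of Sigma_y).
#' @return object of class \code{"sensor_layout"}: list of channels plus
#'   the total row count.
#' @export
sensor_layout <- function(model,
                          imu_links = seq_len(n_links(model)),
                          imu_transforms = NULL,
                          imu_full = FALSE,
                          ft_links = integer(0),
                          ft_transforms = NULL,
                          null_wrench_links = NULL,
                          include_base_null = FALSE,
                          jacc_joints = seq_len(n_joints(model)),
                          var_imu = 1e-4, var_ft = 1e-4,
                          var_jacc = 1e-4, var_null = 1e-4) {
  id_T <- spatial_transform()
  if (is.null(null_wrench_links)) {
    null_wrench_links <- setdiff(seq_len(n_links(model)), c(ft_links))
    if (!include_base_null)
      null_wrench_links <- setdiff(null_wrench_links, 1L)
  }
  channels <- list()
  for (k in seq_along(imu_links)) {
    T <- if (is.null(imu_transforms)) id_T else imu_transforms[[k]]
    channels[[length(channels) + 1L]] <-
      list(kind = "imu", link = imu_links[k], T = T,
           rows = if (imu_full) 6L else 3L, var = var_imu,
           name = paste0("imu:", model$links[[imu_links[k]]]$name))
  }
  for (k in seq_along(ft_links)) {
    T <- if (is.null(ft_transforms)) id_T else ft_transforms[[k]]
    channels[[length(channels) + 1L]] <-
      list(kind = "ft", link = ft_links[k], T = T, rows = 6L, var = var_ft,
           name = paste0("ft:", model$links[[ft_links[k]]]$name))
  }
  for (l in null_wrench_links)
    channels[[length(channels) + 1L]] <-
      list(kind = "null_wrench", link = l, T = id_T, rows = 6L,
           var = var_null,
           name = paste0("null_wrench:", model$links[[l]]$name))
  for (j in jacc_joints)
    channels[[length(channels) + 1L]] <-
      list(kind = "jacc", joint = j, rows = 1L, var = var_jacc,
           name = paste0("jacc:", model$joints[[j]]$name))
  offsets <- cumsum(c(0L, vapply(channels, `[[`, 0L, "rows")))
  structure(list(channels = channels, n_rows = offsets[length(offsets)],
                 offsets = offsets[-length(offsets)], imu_full = imu_full),
            class = "sensor_layout")
}

#' @export
print.sensor_layout <- function(x, ...) {
  kinds <- vapply(x$channels, `[[`, "", "kind")
  cat("sensor layout:", length(x$channels), "channels,", x$n_rows, "rows (",
      paste(names(table(kinds)), table(kinds), collapse = ", "), ")\n")
  invisible(x)
}

#' Rows of the measurement system for one channel
#' @keywords internal
channel_rows <- function(layout, k) {
  layout$offsets[k] + seq_len(layout$channels[[k]]$rows)
}

#' Assemble the stacked measurement system Y d + b_Y = y
#'
#' One block of rows per channel of the \code{\link{sensor_layout}}:
#' accelerometer rows transport the host-link proper sensor acceleration
#' to the sensor frame (the angular-velocity-dependent lever-arm
#' centripetal term enters \code{b_Y}); force/torque rows transport the
#' link external wrench to the sensor frame; joint-acceleration rows
#' select single entries of d.  The row count depends only on the sensors,
#' not on the number of links.
#'
#' @inheritParams build_dynamics_system
#' @param layout a \code{\link{sensor_layout}}.
#' @return list with sparse \code{Y} (\code{n_rows x d}), \code{b}
#'   (\code{n_rows}), \code{sigma} (per-row variances) and \code{kin0}.
#' @export
build_measurement_system <- function(model, layout, s, s_dot,
                                     base_omega = c(0, 0, 0), kin0 = NULL) {
  if (is.null(kin0)) kin0 <- body_kinematics(model, s, s_dot, base_omega)
  trip_i <- trip_j <- trip_x <- list()
  b <- numeric(layout$n_rows)
  sigma <- numeric(layout$n_rows)
  for (k in seq_along(layout$channels)) {
    ch <- layout$channels[[k]]
    rows <- channel_rows(layout, k)
    sigma[rows] <- ch$var
    if (ch$kind == "imu") {
      X <- motion_adjoint(invert_transform(ch$T))     # link -> sensor
      sel <- seq_len(ch$rows)
      w <- kin0$omega_body[, ch$link]
      cent <- as.numeric(t(ch$T$R) %*% cross3(w, cross3(w, ch$T$origin)))
      cols <- d_index(model, "alpha", ch$link)
      block <- X[sel, , drop = FALSE]
      b[rows] <- c(cent, numeric(3))[sel]
    } else if (ch$kind == "ft") {
      cols <- d_index(model, "fx", ch$link)
      block <- force_adjoint(invert_transform(ch$T))  # link -> sensor
    } else if (ch$kind == "null_wrench") {
      cols <- d_index(model, "fx", ch$link)
      block <- diag(6)
    } else {                                          # jacc
      cols <- d_index(model, "sddot", ch$joint)
      block <- matrix(1, 1L, 1L)
    }
    trip_i[[k]] <- rep(rows, times = length(cols))
    trip_j[[k]] <- rep(cols, each = length(rows))
    trip_x[[k]] <- as.numeric(block)
  }
  Y <- Matrix::sparseMatrix(i = unlist(trip_i), j = unlist(trip_j),
                            x = unlist(trip_x),
                            dims = c(layout$n_rows, d_length(model)))
  list(Y = Y, b = b, sigma = sigma, kin0 = kin0)
}

#' Solve the Gaussian MAP problem for the estimation vector d
#'
#' The dynamics constraint \code{D d + b_D = e_D}, \code{e_D ~ N(0,
#' Sigma_D)}, fused with the prior \code{d ~ N(mu_d, Sigma_d)}, gives the
#' intermediate Gaussian \code{(mu_D_bar, Sigma_D_bar)} with information
#' \code{t(D) solve(Sigma_D) D + solve(Sigma_d)}; conditioning on the
#' measurements \code{y = Y d + b_Y + e_y}, \code{e_y ~ N(0, Sigma_y)},
#' yields the posterior
#' \code{Sigma_post = solve(solve(Sigma_D_bar) + t(Y) solve(Sigma_y) Y)}
#' and \code{mu_post = Sigma_post (t(Y) solve(Sigma_y) (y - b_Y) +
#' solve(Sigma_D_bar) mu_D_bar)}.  All covariances are diagonal; the
#' posterior information matrix is assembled sparse and factorized by
#' sparse Cholesky (an error is raised if it is not positive definite).
#'
#' @param Y,b_Y,y measurement system and measured values.
#' @param sigma_y per-row measurement variances (scalar or vector).
#' @param D,b_D dynamics system.
#' @param prior list with \code{Sigma_D} (scalar or length-\code{12 N_B}
#'   vector), \code{Sigma_d}, \code{mu_d} (scalar/vector); see
#'   \code{\link{map_prior}}.
#' @param compute_cov logical; also return the dense posterior covariance
#'   (feasible for moderate \code{d}).
#' @return object of class \code{"gaussian_estimate"}: \code{mean},
#'   \code{chol} (sparse Cholesky factor of the information matrix),
#'   \code{cov} (dense, or \code{NULL}), dimensions.
#' @export
map_solve <- function(Y, b_Y, y, sigma_y, D, b_D, prior = map_prior(),
                      compute_cov = NULL) {
  nd <- ncol(D)
  stopifnot(ncol(Y) == nd, length(y) == nrow(Y), length(b_Y) == nrow(Y),
            length(b_D) == nrow(D))
  sy <- rep_len(sigma_y, nrow(Y))
  sD <- rep_len(prior$Sigma_D, nrow(D))
  sd_ <- rep_len(prior$Sigma_d, nd)
  mu_d <- rep_len(prior$mu_d, nd)
  if (any(sy <= 0) || any(sD <= 0) || any(sd_ <= 0))
    stop("all covariances must be positive")
  Yw <- Matrix::Diagonal(x = 1 / sy) %*% Y    # row-scaled
  Dw <- Matrix::Diagonal(x = 1 / sD) %*% D
  Omega <- Matrix::forceSymmetric(Matrix::crossprod(Y, Yw) +
                                    Matrix::crossprod(D, Dw) +
                                    Matrix::Diagonal(nd, 1 / sd_))
  rhs <- as.numeric(Matrix::crossprod(Yw, y - b_Y) -
                      Matrix::crossprod(Dw, b_D)) + mu_d / sd_
  ch <- tryCatch(Matrix::Cholesky(Omega, LDL = FALSE, perm = TRUE),
                 error = function(e)
                   stop("posterior information matrix is singular or not ",
                        "positive definite: ", conditionMessage(e)))
  mu <- as.numeric(Matrix::solve(ch, rhs, system = "A"))
  if (is.null(compute_cov)) compute_cov <- nd <= 600L
  cov <- NULL
  if (compute_cov) {
    cov <- as.matrix(Matrix::solve(ch, Matrix::Diagonal(nd), system = "A"))
    cov <- (cov + t(cov)) / 2
  }
  structure(list(mean = mu, chol = ch, cov = cov, n = nd),
            class = "gaussian_estimate")
}

#' @export
print.gaussian_estimate <- function(x, ...) {
  cat("Gaussian MAP estimate over", x$n, "stacked unknowns\n")
  invisible(x)
}

#' Prior and model-reliability covariances for the MAP solver
#'
#' Defaults follow the usual trust assignment: small \code{Sigma_D}
#' (trust the dynamic model), large \code{Sigma_d} with zero mean (no
#' prior knowledge of d); measurement variances live in the
#' \code{\link{sensor_layout}}.
#'
#' @param Sigma_D model-equation variance (scalar or per-row vector).
#' @param Sigma_d prior variance on d (scalar or per-entry vector).
#' @param mu_d prior mean on d.
#' @return list passed to \code{\link{map_solve}}.
#' @export
map_prior <- function(Sigma_D = 1e-6, Sigma_d = 1e4, mu_d = 0) {
  list(Sigma_D = Sigma_D, Sigma_d = Sigma_d, mu_d = mu_d)
}

#' Marginal posterior covariance of selected entries
#'
#' @param est a \code{gaussian_estimate}.
#' @param idx integer positions in d.
#' @return dense covariance block.
#' @export
posterior_cov <- function(est, idx) {
  if (!is.null(est$cov)) return(est$cov[idx, idx, drop = FALSE])
  E <- matrix(0, est$n, length(idx))
  E[cbind(idx, seq_along(idx))] <- 1
  X <- as.matrix(Matrix::solve(est$chol, E, system = "A"))
  X[idx, , drop = FALSE]
}

#' Joint torques from the posterior estimate
#'
#' Projects each joint wrench onto its motion freedom subspace:
#' \code{tau_J = t(S_J) f_J}, with variance \code{t(S_J) Sigma(f_J) S_J}.
#'
#' @param est a \code{gaussian_estimate} dimensioned for \code{model}.
#' @param model a \code{multibody_model}.
#' @param variances logical; also compute per-joint posterior variances.
#' @return list with \code{tau} (n-vector) and \code{var} (n-vector of
#'   variances, or \code{NULL}).
#' @export
extract_torques <- function(est, model, variances = TRUE) {
  n <- n_joints(model)
  if (est$n != d_length(model))
    stop("estimate has dimension ", est$n, ", model needs ", d_length(model))
  tau <- v <- numeric(n)
  for (j in seq_len(n)) {
    S <- joint_motion_subspace(model$joints[[j]])
    idx <- d_index(model, "fjoint", j)
    tau[j] <- sum(S * est$mean[idx])
    if (variances)
      v[j] <- as.numeric(t(S) %*% posterior_cov(est, idx) %*% S)
  }
  list(tau = tau, var = if (variances) v else NULL)
}
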