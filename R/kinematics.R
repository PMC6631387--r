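#' Link-pairwise inverse kinematics for a one-DoF joint
#'
#' Recovers the joint position from the measured relative rotation between
#' a link pair.  The objective is the squared norm of the intrinsic Z-Y-X
#' Euler angles of the rotation error \code{t(R_meas) \%*\% R_model(s)},
#' minimized over the joint limits with \code{stats::optimize} after a
#' coarse grid (or locally around \code{init} when warm-started from the
#' previous sample).
#'
#' @param R_meas measured relative rotation of the child link in the
#'   parent link frame.
#' @param joint a \code{\link{model_joint}}.
#' @param init optional warm start (previous-sample solution).
#' @param tol convergence tolerance on the joint position.
#' @param grid_n number of coarse grid points for the global search.
#' @return list with \code{s} (position, clamped inside the limits),
#'   \code{residual} (objective at the solution) and \code{converged}.
#' @export
pairwise_ik <- function(R_meas, joint, init = NULL, tol = 1e-10,
                        grid_n = 181L) {
  check_rotation(R_meas, tol = 1e-6)
  lim <- joint$limits
  if (joint$type == "revolute") {
    lo <- max(lim[1], -pi); hi <- min(lim[2], pi)
  } else {
    if (any(is.infinite(lim)))
      stop("prismatic pairwise IK needs finite joint limits")
    lo <- lim[1]; hi <- lim[2]
  }
  C <- t(R_meas) %*% joint$R_off   # constant factor of the error rotation
  obj <- if (joint$type == "revolute") {
    function(s) sum(euler_zyx(C %*% rot_axis_angle(joint$axis, s))^2)
  } else {
    function(s) sum(euler_zyx(C)^2)  # prismatic: rotation independent of s
  }
  if (joint$type == "prismatic")
    stop("prismatic joints carry no orientation signal; pairwise IK ",
         "requires a revolute joint")
  local_solve <- function(a, b) {
    if (b - a < 4 * tol) return(list(minimum = (a + b) / 2, objective = obj((a + b) / 2)))
    stats::optimize(obj, c(a, b), tol = tol)
  }
  if (!is.null(init)) {
    a <- max(lo, init - 0.6); b <- min(hi, init + 0.6)
    opt <- local_solve(a, b)
    if (opt$objective < 1e-8)
      return(list(s = min(max(opt$minimum, lo), hi),
                  residual = opt$objective, converged = TRUE))
  }
  grid <- seq(lo, hi, length.out = grid_n)
  vals <- vapply(grid, obj, 0)
  k <- which.min(vals)
  a <- grid[max(1L, k - 1L)]; b <- grid[min(grid_n, k + 1L)]
  opt <- local_solve(a, b)
  # keep whichever of the endpoints/refined point is best (bound-active case)
  cand <- c(opt$minimum, lo, hi)
  cv <- vapply(cand, obj, 0)
  i <- which.min(cv)
  list(s = min(max(cand[i], lo), hi), residual = cv[i],
       converged = cv[i] < 1e-6 || i > 1L)
}

#' Joint-angle trajectories from orientation streams
#'
#' Runs \code{\link{pairwise_ik}} for every joint and sample, warm-starting
#' each sample at the previous solution (the first sample starts from the
#' mid-limit point).
#'
#' @param model a \code{multibody_model}.
#' @param orientations list over samples; each element a list over links of
#'   3x3 rotation matrices (inertial from link).
#' @return matrix of joint positions, one row per sample.
#' @export
ik_trajectory <- function(model, orientations) {
  n <- n_joints(model)
  N <- length(orientations)
  S <- matrix(0, N, n)
  for (j in seq_len(n)) {
    jt <- model$joints[[j]]
    lim <- jt$limits
    init <- if (all(is.finite(lim))) mean(lim) else 0
    for (k in seq_len(N)) {
      Rrel <- t(orientations[[k]][[jt$parent]]) %*% orientations[[k]][[jt$child]]
      sol <- pairwise_ik(Rrel, jt, init = init)
      S[k, j] <- sol$s
      init <- sol$s
    }
  }
  S
}

#' Savitzky-Golay smoothing and differentiation
#'
#' Fits a local polynomial of order \code{poly_order} (default cubic) over
#' a sliding window of \code{window} samples and returns the fitted value
#' and its first and second time derivatives at each sample.  Interior
#' samples use the centred window; the first and last half-windows reuse
#' the first/last full window's polynomial evaluated at the off-centre
#' position, so polynomials up to the fit order are reproduced exactly
#' everywhere.
#'
#' @param x numeric vector (or matrix, filtered column-wise).
#' @param dt sampling interval in seconds (e.g. 0.02 at 50 Hz).
#' @param window odd window length, greater than \code{poly_order}.
#' @param poly_order polynomial order of the local fit.
#' @return list with \code{value}, \code{d1}, \code{d2} shaped like
#'   \code{x}.
#' @export
sg_differentiate <- function(x, dt, window = 9L, poly_order = 3L) {
  if (is.matrix(x)) {
    out <- apply(x, 2, sg_differentiate, dt = dt, window = window,
                 poly_order = poly_order, simplify = FALSE)
    return(list(value = sapply(out, `[[`, "value"),
                d1 = sapply(out, `[[`, "d1"),
                d2 = sapply(out, `[[`, "d2")))
  }
  window <- as.integer(window)
  if (window %% 2L != 1L) stop("window must be odd")
  if (window <= poly_order) stop("window must exceed the polynomial order")
  N <- length(x)
  if (N < window) stop("series shorter than the filter window (", window, ")")
  h <- (window - 1L) %/% 2L
  tloc <- seq.int(-h, h)
  V <- outer(tloc, 0:poly_order, `^`)
  P <- solve(crossprod(V), t(V))           # (poly_order+1) x window
  val <- d1 <- d2 <- numeric(N)
  # polynomial coefficient series for all full windows
  idx <- seq_len(N - window + 1L)
  for (i in seq_len(N)) {
    if (i <= h) { w0 <- 1L; off <- i - (h + 1L) }
    else if (i > N - h) { w0 <- N - window + 1L; off <- i - (N - h) }
    else { w0 <- i - h; off <- 0L }
    a <- as.numeric(P %*% x[w0:(w0 + window - 1L)])
    pw <- off^(0:poly_order)
    val[i] <- sum(a * pw)
    d1[i] <- sum(a[-1] * (1:poly_order) * off^(0:(poly_order - 1L)))
    if (poly_order >= 2L)
      d2[i] <- sum(a[-(1:2)] * (2:poly_order) * (1:(poly_order - 1L)) *
                     off^(0:(poly_order - 2L)))
  }
  list(value = val, d1 = d1 / dt, d2 = d2 / dt^2)
}

#' Contact (frame) Jacobian
#'
#' The 6 x (6+n) operator mapping the system velocity
#' \code{nu = (base velocity, joint rates)} to the 6-velocity of a frame
#' rigidly attached to a link, expressed in inertial orientation at the
#' frame origin: \code{v_frame = J_b \%*\% v_base + J_s \%*\% s_dot}.
#'
#' @param model a \code{multibody_model}.
#' @param state a \code{system_state} (only the configuration is used).
#' @param frame link index or name the frame is attached to.
#' @param offset optional \code{spatial_transform} of the frame in the
#'   link frame.
#' @param kin optional precomputed \code{\link{link_kinematics}}.
#' @return 6 x (6+n) matrix; columns 1:6 are \code{J_b}, the rest
#'   \code{J_s}.
#' @export
contact_jacobian <- function(model, state, frame, offset = NULL, kin = NULL) {
  if (is.character(frame)) frame <- link_index(model, frame)
  if (frame < 1L || frame > n_links(model)) stop("unknown frame/link index ", frame)
  if (is.null(kin)) kin <- link_kinematics(model, state)
  n <- n_joints(model)
  pF <- kin$p[, frame]
  if (!is.null(offset)) pF <- pF + as.numeric(kin$R[[frame]] %*% offset$origin)
  J <- matrix(0, 6L, 6L + n)
  J[1:3, 1:3] <- diag(3)
  J[4:6, 4:6] <- diag(3)
  J[1:3, 4:6] <- -skew(pF - kin$p[, 1L])
  path <- path_to_base(model, frame)
  for (i in setdiff(path, 1L)) {
    j <- i - 1L
    jt <- model$joints[[j]]
    a_w <- as.numeric(kin$R[[i]] %*% jt$axis)
    J[, 6L + j] <- if (jt$type == "revolute")
      c(cross3(a_w, pF - kin$p[, i]), a_w) else c(a_w, 0, 0, 0)
  }
  J
}

#' Base velocity from ground-contact constraints
#'
#' During stance the contact frame of the supporting foot has zero
#' 6-velocity, which determines the floating-base velocity from the joint
#' rates: the estimate is the least-squares minimizer of
#' \code{|J_b v + J_s s_dot|^2} over the active contact Jacobians (one
#' foot in single support, the 12-row stack in double support).
#'
#' @param model a \code{multibody_model}.
#' @param state a \code{system_state} carrying the configuration and joint
#'   velocities (the base velocity entry is ignored).
#' @param contact \code{"double"}, \code{"left"} or \code{"right"}.
#' @param frames named list/vector with entries \code{right} and
#'   \code{left}: link indices or names of the two contact frames.
#' @param rank_tol relative singular-value tolerance for the stacked solve.
#' @return list with \code{base_vel} (6-vector, inertial mixed
#'   coordinates), \code{residual} (norm of the stacked constraint
#'   violation) and \code{condition_number}.
#' @export
base_velocity_from_contacts <- function(model, state, contact, frames,
                                        rank_tol = 1e-8) {
  contact <- match.arg(contact, c("double", "left", "right"))
  kin <- link_kinematics(model, state)
  get_J <- function(which) contact_jacobian(model, state, frames[[which]], kin = kin)
  J <- switch(contact,
              right = get_J("right"),
              left = get_J("left"),
              double = rbind(get_J("right"), get_J("left")))
  Jb <- J[, 1:6, drop = FALSE]
  rhs <- -as.numeric(J[, -(1:6), drop = FALSE] %*% state$s_dot)
  sv <- svd(Jb)
  cond <- sv$d[1] / sv$d[6]
  if (sv$d[6] < rank_tol * sv$d[1])
    stop("base-velocity constraint Jacobian is singular to tolerance ",
         "(condition number ", format(cond, digits = 4), ")")
  v <- as.numeric(sv$v %*% ((t(sv$u) %*% rhs) / sv$d))
  list(base_vel = v,
       residual = sqrt(sum((as.numeric(Jb %*% v) - rhs)^2)),
       condition_number = cond)
}
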