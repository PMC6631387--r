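#' Specification of a synthetic rigid-body trajectory
#'
#' Joint trajectories are sinusoids (amplitude, frequency, phase, offset),
#' differentiated analytically so the ground truth carries no numerical
#' differentiation error.  Base motion modes:
#' \describe{
#'   \item{static}{base fixed at the given pose.}
#'   \item{free}{base position sinusoidal per axis and orientation
#'     rotating about a fixed spatial axis with sinusoidal angle.}
#'   \item{rooted}{contact-constrained: a stance schedule alternates which
#'     foot frame is pinned to the ground; the base state follows from the
#'     exact chain recursion rooted at the stance link.  Double-support
#'     samples hold the configuration at zero rates, so both feet are
#'     stationary.}
#' }
#'
#' @param model a \code{multibody_model}.
#' @param joints data frame (one row per joint) with columns \code{amp},
#'   \code{freq} (Hz), \code{phase} (rad), \code{offset}; recycled.
#' @param base list; see Details above.  Fields: \code{mode}, \code{pos0},
#'   \code{R0}, \code{lin_amp}, \code{lin_freq} (3-vectors), \code{ang_axis},
#'   \code{ang_amp}, \code{ang_freq} (scalars).
#' @param schedule for rooted mode: data frame with \code{label}
#'   (\code{double}/\code{right}/\code{left}) and \code{duration} (s).
#' @param frames named list with \code{right}/\code{left} contact link
#'   indices (rooted mode).
#' @param duration trajectory length (s).
#' @param rate sampling rate (Hz), default 50.
#' @param seed integer seed governing every random draw derived from this
#'   spec.
#' @return object of class \code{"trajectory_spec"}.
#' @export
trajectory_spec <- function(model, joints = NULL,
                            base = list(mode = "static"),
                            schedule = NULL, frames = NULL,
                            duration = 2, rate = 50, seed = 1L) {
  n <- n_joints(model)
  if (is.null(joints))
    joints <- data.frame(amp = rep(0.3, n), freq = 0.5, phase = 0, offset = 0)
  joints <- data.frame(amp = rep_len(joints$amp, n),
                       freq = rep_len(joints$freq, n),
                       phase = rep_len(joints$phase, n),
                       offset = rep_len(joints$offset, n))
  base <- utils::modifyList(list(mode = "static", pos0 = c(0, 0, 1),
                                 R0 = diag(3), lin_amp = c(0, 0, 0),
                                 lin_freq = c(0.5, 0.5, 0.5),
                                 lin_phase = c(0, 0, 0),
                                 ang_axis = c(0, 0, 1), ang_amp = 0,
                                 ang_freq = 0.5, ang_phase = 0), base)
  stopifnot(rate > 0, duration > 0)
  # joint excursions must respect the limits
  for (j in seq_len(n)) {
    lim <- model$joints[[j]]$limits
    lo <- joints$offset[j] - abs(joints$amp[j])
    hi <- joints$offset[j] + abs(joints$amp[j])
    if (lo < lim[1] || hi > lim[2])
      stop("joint ", j, " trajectory [", round(lo, 3), ", ", round(hi, 3),
           "] exceeds its limits")
  }
  structure(list(model = model, joints = joints, base = base,
                 schedule = schedule, frames = frames,
                 duration = duration, rate = rate, seed = as.integer(seed)),
            class = "trajectory_spec")
}

joint_eval <- function(joints, t) {
  w <- 2 * pi * joints$freq
  ph <- w * t + joints$phase
  list(s = joints$offset + joints$amp * sin(ph),
       s_dot = joints$amp * w * cos(ph),
       s_ddot = -joints$amp * w^2 * sin(ph))
}

## Base state of a chain rooted at a fixed stance link: exact up-chain
## recursion from the pinned link to the floating base (independent of the
## Jacobian-based estimator).
rooted_base_state <- function(model, foot, foot_T, s, s_dot, s_ddot) {
  path <- rev(path_to_base(model, foot))   # foot first, base last
  R <- foot_T$R; p <- foot_T$origin
  w <- dw <- v <- a <- c(0, 0, 0)
  for (i in path[-length(path)]) {
    j <- i - 1L
    jt <- model$joints[[j]]
    T <- joint_transform(jt, s[j])
    Rla <- R %*% t(T$R)
    r <- as.numeric(Rla %*% T$origin)
    if (jt$type == "revolute") {
      a_w <- as.numeric(R %*% jt$axis)
      odot_I <- oddot_I <- c(0, 0, 0)
      w_la <- w - a_w * s_dot[j]
      dw_la <- dw - a_w * s_ddot[j] - cross3(w, a_w) * s_dot[j]
    } else {
      odot_I <- as.numeric(Rla %*% jt$R_off %*% (jt$axis * s_dot[j]))
      oddot_I <- as.numeric(Rla %*% jt$R_off %*% (jt$axis * s_ddot[j]))
      w_la <- w
      dw_la <- dw
    }
    v_la <- v - cross3(w_la, r) - odot_I
    a_la <- a - cross3(dw_la, r) - cross3(w_la, cross3(w_la, r)) -
      2 * cross3(w_la, odot_I) - oddot_I
    R <- Rla; p <- p - r
    w <- w_la; dw <- dw_la; v <- v_la; a <- a_la
  }
  system_state(R, p, s, base_vel = c(v, w), s_dot = s_dot,
               base_acc = c(a, dw), s_ddot = s_ddot)
}

schedule_labels <- function(schedule, time) {
  edges <- cumsum(schedule$duration)
  idx <- findInterval(time, c(0, edges), rightmost.closed = TRUE,
                      left.open = TRUE)
  idx[idx < 1L] <- 1L
  idx[idx > nrow(schedule)] <- nrow(schedule)
  list(label = as.character(schedule$label)[idx], interval = idx)
}

#' Simulate a rigid-body-consistent trajectory with ground truth
#'
#' Evaluates the trajectory spec sample by sample, computes exact
#' whole-body kinematics (analytic differentiation of the generators),
#' allocates the external wrenches that make the motion dynamically
#' consistent (free mode: the balancing wrench acts on the base; rooted
#' mode: on the stance foot, split by minimum-norm allocation in double
#' support), and assembles the stacked estimation vector at every sample.
#'
#' @param spec a \code{\link{trajectory_spec}}.
#' @param gravity inertial gravity vector.
#' @return object of class \code{"ground_truth"}: per-sample lists
#'   \code{states}, \code{kin}, \code{f_ext}, \code{joint_wrench},
#'   \code{tau} (matrix N x n), \code{d_true} (matrix d x N),
#'   \code{labels} (contact labels or \code{NULL}), \code{time},
#'   \code{rate}, \code{model}.
#' @export
simulate_trajectory <- function(spec, gravity = default_gravity()) {
  model <- spec$model
  nb <- n_links(model)
  n <- n_joints(model)
  N <- floor(spec$duration * spec$rate) + 1L
  time <- (seq_len(N) - 1L) / spec$rate
  b <- spec$base
  labels <- NULL
  if (b$mode == "rooted") {
    if (is.null(spec$schedule) || is.null(spec$frames))
      stop("rooted base mode needs a stance schedule and contact frames")
    if (any(!spec$schedule$label %in% c("double", "left", "right")))
      stop("schedule labels must be double/left/right")
    lab <- schedule_labels(spec$schedule, time)
    labels <- factor(lab$label, levels = c("double", "right", "left"))
  }
  states <- vector("list", N)
  for (k in seq_len(N)) {
    je <- joint_eval(spec$joints, time[k])
    if (b$mode == "static") {
      states[[k]] <- system_state(b$R0, b$pos0, je$s, s_dot = je$s_dot,
                                  s_ddot = je$s_ddot)
    } else if (b$mode == "free") {
      wl <- 2 * pi * b$lin_freq
      phl <- wl * time[k] + b$lin_phase
      pos <- b$pos0 + b$lin_amp * sin(phl)
      vel <- b$lin_amp * wl * cos(phl)
      acc <- -b$lin_amp * wl^2 * sin(phl)
      wa <- 2 * pi * b$ang_freq
      th <- b$ang_amp * sin(wa * time[k] + b$ang_phase)
      thd <- b$ang_amp * wa * cos(wa * time[k] + b$ang_phase)
      thdd <- -b$ang_amp * wa^2 * sin(wa * time[k] + b$ang_phase)
      u <- b$ang_axis / sqrt(sum(b$ang_axis^2))
      Rb <- b$R0 %*% rot_axis_angle(u, th)
      u_I <- as.numeric(b$R0 %*% u)
      states[[k]] <- system_state(Rb, pos, je$s,
                                  base_vel = c(vel, u_I * thd),
                                  s_dot = je$s_dot,
                                  base_acc = c(acc, u_I * thdd),
                                  s_ddot = je$s_ddot)
    } else if (b$mode == "rooted") {
      if (labels[k] == "double") {
        states[[k]] <- rooted_base_state(model, spec$frames$right,
                                         spatial_transform(),
                                         je$s, 0 * je$s, 0 * je$s)
      } else {
        foot <- if (labels[k] == "right") spec$frames$right else spec$frames$left
        states[[k]] <- rooted_base_state(model, foot, spatial_transform(),
                                         je$s, je$s_dot, je$s_ddot)
      }
    } else stop("unknown base mode '", b$mode, "'")
  }
  kin <- lapply(states, function(st) link_kinematics(model, st, gravity))
  f_ext <- vector("list", N)
  joint_wrench <- vector("list", N)
  tau <- matrix(0, N, n)
  d_true <- matrix(0, d_length(model), N)
  for (k in seq_len(N)) {
    id0 <- rnea_oracle(model, states[[k]], gravity = gravity, kin = kin[[k]])
    fx <- matrix(0, 6L, nb)
    wB <- id0$base_residual
    if (b$mode == "rooted") {
      Xstar <- function(foot) {
        TBf <- spatial_transform(t(kin[[k]]$R[[1L]]) %*% kin[[k]]$R[[foot]],
                                 as.numeric(t(kin[[k]]$R[[1L]]) %*%
                                              (kin[[k]]$p[, foot] - kin[[k]]$p[, 1L])))
        force_adjoint(TBf)
      }
      if (labels[k] == "double") {
        A <- cbind(Xstar(spec$frames$right), Xstar(spec$frames$left))
        f12 <- as.numeric(t(A) %*% solve(A %*% t(A), wB))   # minimum norm
        fx[, spec$frames$right] <- f12[1:6]
        fx[, spec$frames$left] <- f12[7:12]
      } else {
        foot <- if (labels[k] == "right") spec$frames$right else spec$frames$left
        fx[, foot] <- solve(Xstar(foot), wB)
      }
    } else {
      fx[, 1L] <- wB   # balancing wrench acts on the base
    }
    id <- rnea_oracle(model, states[[k]], f_ext = fx, gravity = gravity,
                      kin = kin[[k]])
    f_ext[[k]] <- fx
    joint_wrench[[k]] <- id$joint_wrench
    tau[k, ] <- id$tau
    d <- numeric(d_length(model))
    for (i in seq_len(nb)) {
      d[d_index(model, "alpha", i)] <- kin[[k]]$alpha_g[, i]
      d[d_index(model, "fx", i)] <- fx[, i]
    }
    for (j in seq_len(n)) {
      d[d_index(model, "fjoint", j)] <- id$joint_wrench[, j]
      d[d_index(model, "sddot", j)] <- states[[k]]$s_ddot[j]
    }
    d_true[, k] <- d
  }
  structure(list(model = model, time = time, rate = spec$rate,
                 states = states, kin = kin, f_ext = f_ext,
                 joint_wrench = joint_wrench, tau = tau, d_true = d_true,
                 labels = labels, spec = spec, gravity = gravity),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("synthetic ground truth:", length(x$time), "samples at", x$rate,
      "Hz,", n_links(x$model), "links\n")
  invisible(x)
}

#' Simulate sensor measurement streams from ground truth
#'
#' Computes every channel of the sensor layout by its physical forward
#' model evaluated on the exact link kinematics (accelerometer channels
#' from the sensor-frame acceleration, not via the measurement matrix, so
#' the two form an independent cross-check) and adds i.i.d. zero-mean
#' Gaussian noise.  All randomness derives from \code{seed}.
#'
#' @param gt a \code{\link{simulate_trajectory}} result.
#' @param layout a \code{\link{sensor_layout}}.
#' @param noise_sd named vector of per-kind noise standard deviations,
#'   e.g. \code{c(imu = 0.01, ft = 0.1, jacc = 0.01, null_wrench = 0)};
#'   missing kinds default to 0 (noiseless).
#' @param seed integer seed.
#' @return object of class \code{"mapdyn_streams"} consumed by
#'   \code{\link{estimate_dynamics}}: exact joint/base kinematic inputs
#'   plus the noisy measurement matrix \code{y} (rows = channels).
#' @export
generate_measurements <- function(gt, layout, noise_sd = c(), seed = 1L) {
  model <- gt$model
  N <- length(gt$time)
  sd_of <- function(kind) {
    v <- noise_sd[kind]
    if (is.na(v) || is.null(v)) 0 else as.numeric(v)
  }
  y <- matrix(0, layout$n_rows, N)
  for (k in seq_len(N)) {
    kin <- gt$kin[[k]]
    for (c in seq_along(layout$channels)) {
      ch <- layout$channels[[c]]
      rows <- channel_rows(layout, c)
      if (ch$kind == "imu") {
        L <- ch$link
        RS <- kin$R[[L]] %*% ch$T$R
        oS <- as.numeric(kin$R[[L]] %*% ch$T$origin)
        pddS <- kin$pddot[, L] + cross3(kin$omegadot_I[, L], oS) +
          cross3(kin$omega_I[, L], cross3(kin$omega_I[, L], oS))
        a_sensor <- c(as.numeric(t(RS) %*% (pddS - gt$gravity)),
                      as.numeric(t(RS) %*% kin$omegadot_I[, L]))
        y[rows, k] <- a_sensor[seq_len(ch$rows)]
      } else if (ch$kind == "ft") {
        y[rows, k] <- as.numeric(force_adjoint(invert_transform(ch$T)) %*%
                                   gt$f_ext[[k]][, ch$link])
      } else if (ch$kind == "null_wrench") {
        y[rows, k] <- 0
      } else {
        y[rows, k] <- gt$states[[k]]$s_ddot[ch$joint]
      }
    }
  }
  set.seed(seed)
  for (c in seq_along(layout$channels)) {
    ch <- layout$channels[[c]]
    sdv <- sd_of(ch$kind)
    if (sdv > 0) {
      rows <- channel_rows(layout, c)
      y[rows, ] <- y[rows, ] + matrix(stats::rnorm(length(rows) * N, 0, sdv),
                                      length(rows), N)
    }
  }
  s <- t(vapply(gt$states, `[[`, numeric(n_joints(model)), "s"))
  s_dot <- t(vapply(gt$states, `[[`, numeric(n_joints(model)), "s_dot"))
  base_omega <- vapply(seq_len(N), function(k) gt$kin[[k]]$omega_body[, 1L],
                       numeric(3))
  base_alpha <- vapply(seq_len(N), function(k) gt$kin[[k]]$alpha_g[, 1L],
                       numeric(6))
  orientations <- lapply(gt$kin, `[[`, "R")
  structure(list(time = gt$time, rate = gt$rate, y = y, layout = layout,
                 s = s, s_dot = s_dot, base_omega = base_omega,
                 base_alpha = base_alpha, orientations = orientations,
                 base_R = lapply(gt$states, `[[`, "base_R"),
                 base_pos = vapply(gt$states, `[[`, numeric(3), "base_pos"),
                 labels = gt$labels, frames = gt$spec$frames),
            class = "mapdyn_streams")
}

#' Synthetic vertical ground-reaction forces for a stance schedule
#'
#' Piecewise-linear force traces: double support splits the body weight
#' evenly, single support loads one shoe fully, and each schedule
#' boundary is bridged by a linear ramp of the given transition time.
#' Also returns the labels implied by the schedule, for comparison with
#' \code{\link{classify_contacts}}.
#'
#' @param schedule data frame with columns \code{label}
#'   (\code{double}/\code{right}/\code{left}) and \code{duration} (s).
#' @param weight body weight (N).
#' @param transition ramp time at each boundary (s).
#' @param rate sampling rate (Hz).
#' @return list with \code{time}, \code{rf_fz}, \code{lf_fz},
#'   \code{labels} (factor) and \code{transition_mask} (TRUE on ramp
#'   samples).
#' @export
generate_gait_forces <- function(schedule, weight = 700, transition = 0.2,
                                 rate = 50) {
  stopifnot(all(schedule$label %in% c("double", "right", "left")),
            all(schedule$duration > 0), weight > 0, transition >= 0)
  total <- sum(schedule$duration)
  N <- floor(total * rate) + 1L
  time <- (seq_len(N) - 1L) / rate
  plateau <- function(lab) switch(lab, double = c(weight / 2, weight / 2),
                                  right = c(weight, 0), left = c(0, weight))
  lab <- schedule_labels(schedule, time)
  vals <- vapply(as.character(schedule$label), plateau, numeric(2))
  edges <- cumsum(schedule$duration)[-nrow(schedule)]
  rf <- vals[1, lab$interval]
  lf <- vals[2, lab$interval]
  mask <- rep(FALSE, N)
  if (transition > 0 && length(edges) > 0) {
    for (e in seq_along(edges)) {
      t0 <- edges[e] - transition / 2
      t1 <- edges[e] + transition / 2
      sel <- time >= t0 & time <= t1
      mask <- mask | sel
      frac <- (time[sel] - t0) / transition
      rf[sel] <- vals[1, e] + frac * (vals[1, e + 1] - vals[1, e])
      lf[sel] <- vals[2, e] + frac * (vals[2, e + 1] - vals[2, e])
    }
  }
  list(time = time, rf_fz = rf, lf_fz = lf,
       labels = factor(lab$label, levels = c("double", "right", "left")),
       transition_mask = mask)
}

#' Simple articulated test models
#'
#' \code{make_chain_model} builds a serial floating-base chain of
#' \code{nb} links (desk-scale masses and segment lengths, joint axes
#' cycling x/y/z or drawn at random); \code{make_biped_model} builds the
#' default five-link test body: a pelvis-like base with two two-link legs
#' whose lower-leg frames serve as contact feet; \code{make_humanoid_model}
#' builds a large balanced tree (default 67 links, 66 DoFs) used purely as
#' a scale test, with no physiological fidelity claimed.
#'
#' @param nb number of links including the base.
#' @param seed if non-NULL, joint axes/origins and inertias are drawn
#'   reproducibly at random; otherwise a fixed deterministic geometry.
#' @return a \code{multibody_model}.
#' @export
make_chain_model <- function(nb = 3L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rand <- !is.null(seed)
  axes <- list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  links <- vector("list", nb)
  joints <- vector("list", nb - 1L)
  for (i in seq_len(nb)) {
    m <- if (rand) stats::runif(1, 1, 10) else 2 + i
    com <- if (rand) stats::runif(3, -0.1, 0.1) else c(0, 0, -0.2)
    Irot <- diag(if (rand) stats::runif(3, 0.01, 0.2) else rep(0.05, 3))
    links[[i]] <- list(name = paste0("link", i - 1L),
                       inertia = spatial_inertia(m, com,
                                                 inertia_at_origin(Irot, m, com)))
  }
  for (j in seq_len(nb - 1L)) {
    ax <- if (rand) { v <- stats::rnorm(3); v / sqrt(sum(v^2)) } else axes[[(j - 1L) %% 3L + 1L]]
    org <- if (rand) c(stats::runif(2, -0.1, 0.1), -stats::runif(1, 0.2, 0.5)) else c(0, 0, -0.4)
    joints[[j]] <- model_joint(paste0("joint", j), j, j + 1L, "revolute",
                               ax, org, limits = c(-2.5, 2.5))
  }
  multibody_model(links, joints)
}

#' @rdname make_chain_model
#' @export
make_biped_model <- function() {
  leg_inertia <- function(m) spatial_inertia(m, c(0, 0, -0.2),
    inertia_at_origin(diag(c(0.08, 0.08, 0.01)), m, c(0, 0, -0.2)))
  links <- list(
    list(name = "pelvis",
         inertia = spatial_inertia(10, c(0, 0, 0.1),
                                   inertia_at_origin(diag(c(0.2, 0.15, 0.1)),
                                                     10, c(0, 0, 0.1)))),
    list(name = "right_thigh", inertia = leg_inertia(6)),
    list(name = "left_thigh", inertia = leg_inertia(6)),
    list(name = "right_shank", inertia = leg_inertia(3)),
    list(name = "left_shank", inertia = leg_inertia(3)))
  joints <- list(
    model_joint("right_hip", 1L, 2L, "revolute", c(0, 1, 0), c(0, -0.12, 0),
                limits = c(-2.0, 2.0)),
    model_joint("left_hip", 1L, 3L, "revolute", c(0, 1, 0), c(0, 0.12, 0),
                limits = c(-2.0, 2.0)),
    model_joint("right_knee", 2L, 4L, "revolute", c(0, 1, 0), c(0, 0, -0.45),
                limits = c(-2.3, 0.1)),
    model_joint("left_knee", 3L, 5L, "revolute", c(0, 1, 0), c(0, 0, -0.45),
                limits = c(-2.3, 0.1)))
  multibody_model(links, joints)
}

#' @rdname make_chain_model
#' @export
make_humanoid_model <- function(nb = 67L) {
  axes <- list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  links <- vector("list", nb)
  joints <- vector("list", nb - 1L)
  for (i in seq_len(nb)) {
    m <- 1 + (i %% 5)
    com <- c(0, 0, -0.1)
    links[[i]] <- list(name = paste0("seg", i - 1L),
                       inertia = spatial_inertia(m, com,
                         inertia_at_origin(diag(c(0.02, 0.02, 0.005)), m, com)))
  }
  for (j in seq_len(nb - 1L)) {
    child <- j + 1L
    parent <- max(1L, child %/% 2L)   # balanced binary tree
    joints[[j]] <- model_joint(paste0("j", j), parent, child, "revolute",
                               axes[[(j - 1L) %% 3L + 1L]],
                               c(0.05 * ((j %% 3) - 1), 0, -0.2),
                               limits = c(-2.5, 2.5))
  }
  multibody_model(links, joints)
}
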