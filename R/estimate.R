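#' Configuration of the whole-body estimator
#'
#' @param Sigma_D model-equation variance (trust in the rigid-body model);
#'   scalar or per-row vector.
#' @param Sigma_d prior variance on the estimation vector (large = no
#'   prior knowledge).
#' @param mu_d prior mean on the estimation vector.
#' @param sg_window,sg_order Savitzky-Golay window (samples, odd) and
#'   polynomial order used when joint rates are not supplied.
#' @param contact_scale scale factor on the self-tuned contact threshold.
#' @param variances logical; compute per-joint posterior torque variances
#'   (requires marginal covariance solves; default on for moderate model
#'   sizes).
#' @param compute_cov \code{NULL} (auto), or logical: keep the full dense
#'   posterior covariance per sample.
#' @return list of class \code{"map_config"}.
#' @export
map_config <- function(Sigma_D = 1e-6, Sigma_d = 1e4, mu_d = 0,
                       sg_window = 9L, sg_order = 3L, contact_scale = 1,
                       variances = NULL, compute_cov = FALSE) {
  structure(list(Sigma_D = Sigma_D, Sigma_d = Sigma_d, mu_d = mu_d,
                 sg_window = sg_window, sg_order = sg_order,
                 contact_scale = contact_scale, variances = variances,
                 compute_cov = compute_cov),
            class = "map_config")
}

#' Simultaneous floating-base estimation of whole-body dynamics
#'
#' The main fitting function: runs the full per-sample pipeline on
#' measurement streams — joint angles by link-pairwise inverse kinematics
#' (skipped when the stream already carries them), joint rates by
#' Savitzky-Golay differentiation (skipped likewise), contact
#' classification from the vertical shoe forces, contact-constrained
#' base-velocity estimation, then the Gaussian maximum-a-posteriori solve
#' of the stacked dynamics/measurement system and the joint-torque
#' projection.  Samples are estimated independently (no temporal
#' smoothing across the posterior).
#'
#' @param model a \code{multibody_model}.
#' @param streams a \code{mapdyn_streams} object (see
#'   \code{\link{generate_measurements}} and the CSV readers): fields
#'   \code{time}, \code{rate}, \code{y} (channel rows x samples),
#'   \code{base_omega} (3 x N, base coordinates), \code{base_alpha}
#'   (6 x N, known base proper sensor acceleration), and either \code{s}
#'   (+ optional \code{s_dot}) or \code{orientations}; optional
#'   \code{base_R}/\code{base_pos}, \code{rf_fz}/\code{lf_fz} or
#'   \code{labels}, \code{frames}.
#' @param layout the \code{\link{sensor_layout}} describing \code{y};
#'   defaults to the one attached to the streams.
#' @param config a \code{\link{map_config}}.
#' @param frames named list with \code{right}/\code{left} contact link
#'   indices; defaults to the one attached to the streams.
#' @return object of class \code{"map_dynamics"} with per-sample posterior
#'   means, joint torques and their posterior standard deviations,
#'   measurement residuals, contact labels and estimated base velocities.
#' @seealso \code{\link{coef.map_dynamics}},
#'   \code{\link{residuals.map_dynamics}}, \code{\link{plot.map_dynamics}}
#' @export
estimate_dynamics <- function(model, streams, layout = streams$layout,
                              config = map_config(),
                              frames = streams$frames) {
  if (is.null(layout)) stop("a sensor layout is required")
  N <- length(streams$time)
  n <- n_joints(model)
  nd <- d_length(model)
  rate <- streams$rate

  # --- kinematics stage -------------------------------------------------
  s <- streams$s
  if (is.null(s)) {
    if (is.null(streams$orientations))
      stop("streams must carry joint positions or orientation streams")
    s <- ik_trajectory(model, streams$orientations)
  }
  s <- matrix(s, N, n)
  if (!is.null(streams$s_dot)) {
    s_dot <- matrix(streams$s_dot, N, n)
    s_ddot_kin <- if (!is.null(streams$s_ddot)) matrix(streams$s_ddot, N, n)
                  else NULL
  } else {
    sg <- sg_differentiate(s, 1 / rate, config$sg_window, config$sg_order)
    s <- matrix(sg$value, N, n)
    s_dot <- matrix(sg$d1, N, n)
    s_ddot_kin <- matrix(sg$d2, N, n)
  }

  # --- contact stage ----------------------------------------------------
  labels <- streams$labels
  threshold <- NA_real_
  if (is.null(labels) && !is.null(streams$rf_fz)) {
    threshold <- compute_threshold(streams$rf_fz, streams$lf_fz,
                                   config$contact_scale)
    labels <- classify_contacts(streams$rf_fz, streams$lf_fz, threshold)
  }
  base_vel <- matrix(NA_real_, 6L, N)
  if (!is.null(labels) && !is.null(frames) && !is.null(streams$base_R)) {
    for (k in seq_len(N)) {
      st <- system_state(streams$base_R[[k]], streams$base_pos[, k],
                         s[k, ], s_dot = s_dot[k, ])
      bv <- base_velocity_from_contacts(model, st, as.character(labels[k]),
                                        frames)
      base_vel[, k] <- bv$base_vel
    }
  }

  # --- MAP stage --------------------------------------------------------
  prior <- map_prior(config$Sigma_D, config$Sigma_d, config$mu_d)
  variances <- config$variances
  if (is.null(variances)) variances <- nd <= 600L
  mu <- matrix(0, nd, N)
  tau <- tau_sd <- matrix(0, N, n)
  resid <- matrix(0, layout$n_rows, N)
  for (k in seq_len(N)) {
    kin0 <- body_kinematics(model, s[k, ], s_dot[k, ], streams$base_omega[, k])
    dyn <- build_dynamics_system(model, s[k, ], s_dot[k, ],
                                 streams$base_omega[, k],
                                 streams$base_alpha[, k], kin0 = kin0)
    meas <- build_measurement_system(model, layout, s[k, ], s_dot[k, ],
                                     kin0 = kin0)
    est <- map_solve(meas$Y, meas$b, streams$y[, k], meas$sigma,
                     dyn$D, dyn$b, prior, compute_cov = config$compute_cov)
    mu[, k] <- est$mean
    tq <- extract_torques(est, model, variances = variances)
    tau[k, ] <- tq$tau
    tau_sd[k, ] <- if (variances) sqrt(tq$var) else NA_real_
    resid[, k] <- streams$y[, k] - (as.numeric(meas$Y %*% est$mean) + meas$b)
  }
  colnames(tau) <- colnames(tau_sd) <-
    vapply(model$joints, `[[`, "", "name")
  structure(list(model = model, layout = layout, config = config,
                 time = streams$time, rate = rate,
                 s = s, s_dot = s_dot, s_ddot_kin = s_ddot_kin,
                 labels = labels, threshold = threshold,
                 base_vel = base_vel, mu = mu, tau = tau, tau_sd = tau_sd,
                 residuals = resid, streams = streams, frames = frames),
            class = "map_dynamics")
}

#' @export
print.map_dynamics <- function(x, ...) {
  cat("Floating-base MAP dynamics estimate\n")
  cat("  model: ", n_links(x$model), " links, ", n_joints(x$model),
      " joints; ", length(x$time), " samples at ", x$rate, " Hz\n", sep = "")
  cat("  stacked unknowns per sample:", d_length(x$model), "\n")
  if (!is.null(x$labels))
    cat("  contact: ", paste(names(table(x$labels)), table(x$labels),
                             sep = "=", collapse = ", "), "\n", sep = "")
  cat("  torque range [N m]: ",
      paste(format(range(x$tau), digits = 3), collapse = " .. "), "\n", sep = "")
  invisible(x)
}

#' @export
summary.map_dynamics <- function(object, ...) {
  kinds <- unlist(lapply(seq_along(object$layout$channels), function(k)
    rep(object$layout$channels[[k]]$kind, object$layout$channels[[k]]$rows)))
  res_rms <- tapply(sqrt(rowMeans(object$residuals^2)), kinds, mean)
  out <- list(n_samples = length(object$time),
              torque_rms = sqrt(colMeans(object$tau^2)),
              torque_mean_sd = colMeans(object$tau_sd),
              residual_rms_by_kind = res_rms,
              contact_table = if (!is.null(object$labels))
                table(object$labels) else NULL)
  class(out) <- "summary.map_dynamics"
  out
}

#' @export
print.summary.map_dynamics <- function(x, ...) {
  cat("MAP dynamics estimate over", x$n_samples, "samples\n\nJoint torque RMS [N m]:\n")
  print(round(x$torque_rms, 4))
  if (!all(is.na(x$torque_mean_sd))) {
    cat("\nMean posterior torque SD [N m]:\n")
    print(signif(x$torque_mean_sd, 3))
  }
  cat("\nMeasurement residual RMS by channel kind:\n")
  print(signif(x$residual_rms_by_kind, 3))
  if (!is.null(x$contact_table)) {
    cat("\nContact classification:\n")
    print(x$contact_table)
  }
  invisible(x)
}

#' Estimated joint torque trajectories
#' @param object a \code{map_dynamics} fit.
#' @param ... unused.
#' @return samples x joints matrix of torques (N m).
#' @export
coef.map_dynamics <- function(object, ...) object$tau

#' Measurement residuals of the posterior mean
#' @param object a \code{map_dynamics} fit.
#' @param ... unused.
#' @return channels x samples matrix \code{y - (Y mu + b_Y)}.
#' @export
residuals.map_dynamics <- function(object, ...) object$residuals

#' Fitted (reconstructed) measurements
#' @param object a \code{map_dynamics} fit.
#' @param ... unused.
#' @return channels x samples matrix \code{Y mu + b_Y}.
#' @export
fitted.map_dynamics <- function(object, ...)
  object$streams$y - object$residuals

#' Plot estimated joint torques
#' @param x a \code{map_dynamics} fit.
#' @param joints joint indices to draw.
#' @param ... passed to \code{matplot}.
#' @export
plot.map_dynamics <- function(x, joints = seq_len(ncol(x$tau)), ...) {
  graphics::matplot(x$time, x$tau[, joints, drop = FALSE], type = "l",
                    lty = 1, xlab = "time [s]", ylab = "joint torque [N m]",
                    ...)
  graphics::legend("topright", legend = colnames(x$tau)[joints],
                   col = seq_along(joints), lty = 1, cex = 0.8, bty = "n")
  invisible(x)
}

#' Draw samples from the per-sample posterior
#'
#' Re-solves the MAP system for one time sample with the full posterior
#' covariance and returns Gaussian draws of the stacked vector d.
#'
#' @param object a \code{map_dynamics} fit.
#' @param nsim number of draws.
#' @param seed optional integer seed.
#' @param sample time-sample index.
#' @param ... unused.
#' @return matrix with \code{nsim} columns, one posterior draw of d each.
#' @export
simulate.map_dynamics <- function(object, nsim = 1, seed = NULL,
                                  sample = 1L, ...) {
  if (!is.null(seed)) set.seed(seed)
  st <- object$streams
  k <- sample
  kin0 <- body_kinematics(object$model, object$s[k, ], object$s_dot[k, ],
                          st$base_omega[, k])
  dyn <- build_dynamics_system(object$model, object$s[k, ], object$s_dot[k, ],
                               st$base_omega[, k], st$base_alpha[, k],
                               kin0 = kin0)
  meas <- build_measurement_system(object$model, object$layout,
                                   object$s[k, ], object$s_dot[k, ],
                                   kin0 = kin0)
  prior <- map_prior(object$config$Sigma_D, object$config$Sigma_d,
                     object$config$mu_d)
  est <- map_solve(meas$Y, meas$b, st$y[, k], meas$sigma, dyn$D, dyn$b,
                   prior, compute_cov = TRUE)
  L <- chol(est$cov + diag(1e-12, est$n))
  est$mean + t(L) %*% matrix(stats::rnorm(est$n * nsim), est$n, nsim)
}
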