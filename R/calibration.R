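#' Regressor of the sensor-position measurement equation
#'
#' An accelerometer rigidly mounted at the (unknown) position \code{o_S}
#' of its host link reads, in its own frame,
#' \code{a_S = t(R_S) (pddot_L + (S(omegadot) + S(omega)^2) R_L o_S - g)}.
#' Rearranged per sample into \code{A o_S = b} with
#' \code{A = (S(omegadot) + S(omega)^2) R_L} and
#' \code{b = R_S a_S - (pddot_L - g)}, all in inertial coordinates.
#'
#' @param a_S sensor-frame linear proper acceleration (3-vector, m/s^2).
#' @param omega_L,omegadot_L link angular velocity/acceleration, inertial
#'   coordinates (rad/s, rad/s^2).
#' @param R_L,R_S link and sensor orientations (inertial from frame).
#' @param pddot_L link-origin linear acceleration, inertial (m/s^2).
#' @param gravity inertial gravity vector.
#' @return list with \code{A} (3x3) and \code{b} (3-vector).
#' @export
build_regressor <- function(a_S, omega_L, omegadot_L, R_L, R_S, pddot_L,
                            gravity = default_gravity()) {
  A <- (skew(omegadot_L) + skew(omega_L) %*% skew(omega_L)) %*% R_L
  b <- as.numeric(R_S %*% a_S) - (pddot_L - gravity)
  list(A = A, b = b)
}

#' Least-squares estimation of a sensor position in its link frame
#'
#' Stacks the per-sample regressors of \code{\link{build_regressor}} and
#' solves \code{argmin |Abar o_S - bbar|^2} by singular value
#' decomposition.  Near-static samples (both \code{|omega|} and
#' \code{|omegadot|} below \code{min_motion}) carry no position signal and
#' are dropped by default.  If the stacked regressor is rank deficient the
#' offset is unobservable and an error reports the null-space direction
#' (e.g. a trial spinning about a single axis cannot resolve the offset
#' component along that axis).
#'
#' @param samples data frame with one row per sample and columns
#'   \code{ax, ay, az} (sensor-frame acceleration), \code{wx, wy, wz},
#'   \code{dwx, dwy, dwz} (link angular velocity/acceleration, inertial),
#'   \code{qlw, qlx, qly, qlz}, \code{qsw, qsx, qsy, qsz} (link and sensor
#'   orientation quaternions, w-x-y-z), \code{alx, aly, alz} (link origin
#'   linear acceleration, inertial).
#' @param gravity inertial gravity vector.
#' @param min_motion rad/s (and rad/s^2) threshold below which a sample is
#'   treated as static and dropped; set to \code{0} to keep all samples.
#' @param rank_tol singular values below \code{rank_tol * max(sv)} are
#'   treated as zero.
#' @return list with \code{position} (estimated \code{o_S}, link frame, m)
#'   and \code{diagnostics} (residual norm, RMS residual, condition
#'   number, samples used).
#' @export
estimate_sensor_position <- function(samples, gravity = default_gravity(),
                                     min_motion = 1e-3, rank_tol = 1e-8) {
  stopifnot(is.data.frame(samples), nrow(samples) >= 1L)
  keep <- logical(nrow(samples))
  rows_A <- vector("list", nrow(samples))
  rows_b <- vector("list", nrow(samples))
  for (i in seq_len(nrow(samples))) {
    r <- samples[i, ]
    w <- c(r$wx, r$wy, r$wz)
    dw <- c(r$dwx, r$dwy, r$dwz)
    if (sqrt(sum(w^2)) < min_motion && sqrt(sum(dw^2)) < min_motion) next
    keep[i] <- TRUE
    reg <- build_regressor(c(r$ax, r$ay, r$az), w, dw,
                           quat_to_rot(c(r$qlw, r$qlx, r$qly, r$qlz)),
                           quat_to_rot(c(r$qsw, r$qsx, r$qsy, r$qsz)),
                           c(r$alx, r$aly, r$alz), gravity)
    rows_A[[i]] <- reg$A
    rows_b[[i]] <- reg$b
  }
  if (!any(keep))
    stop("sensor position unobservable: all samples are static ",
         "(the regressor is identically zero; any offset direction is in ",
         "the null space)")
  A <- do.call(rbind, rows_A[keep])
  b <- unlist(rows_b[keep])
  sv <- svd(A)
  rank <- sum(sv$d > rank_tol * sv$d[1])
  if (rank < 3L) {
    null_dirs <- sv$v[, seq.int(rank + 1L, 3L), drop = FALSE]
    stop("sensor position unobservable: stacked regressor has rank ", rank,
         "; offset components along the link-frame direction(s) [",
         paste(apply(round(null_dirs, 4), 2, paste, collapse = " "),
               collapse = "; "),
         "] are in the null space (excite rotation about two non-parallel axes)")
  }
  o <- as.numeric(sv$v %*% ((t(sv$u) %*% b) / sv$d))
  res <- as.numeric(A %*% o) - b
  list(position = o,
       diagnostics = list(residual_norm = sqrt(sum(res^2)),
                          rms_residual = sqrt(mean(res^2)),
                          condition_number = sv$d[1] / sv$d[3],
                          n_used = sum(keep), n_total = nrow(samples)))
}
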