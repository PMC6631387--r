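#' CSV stream readers and writers
#'
#' Plain-text interchange formats for the pipeline stages.  Orientation
#' streams are long-format CSV with columns \code{time, frame, qw, qx,
#' qy, qz} (quaternion convention w-x-y-z, inertial from frame); joint
#' trajectories are wide CSV with \code{time} then one column per joint
#' (suffixes \code{_dot}/\code{_ddot} for rates); vertical forces are
#' \code{time, rf_fz, lf_fz}; calibration logs follow the column order
#' documented in \code{\link{estimate_sensor_position}}.
#'
#' @name mapdyn-io
NULL

#' @rdname mapdyn-io
#' @param orientations list over samples of lists over frames of rotation
#'   matrices.
#' @param time sample times (s).
#' @param frame_names character names of the frames.
#' @param path file path.
#' @export
write_orientation_csv <- function(orientations, time, frame_names, path) {
  rows <- list()
  for (k in seq_along(time)) {
    for (f in seq_along(frame_names)) {
      q <- rot_to_quat(orientations[[k]][[f]])
      rows[[length(rows) + 1L]] <-
        data.frame(time = time[k], frame = frame_names[f],
                   qw = q[1], qx = q[2], qy = q[3], qz = q[4])
    }
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname mapdyn-io
#' @export
read_orientation_csv <- function(path) {
  df <- utils::read.csv(path)
  times <- sort(unique(df$time))
  frames <- unique(df$frame)
  orientations <- lapply(times, function(tk) {
    sub <- df[df$time == tk, ]
    out <- lapply(frames, function(f) {
      r <- sub[sub$frame == f, ]
      quat_to_rot(c(r$qw, r$qx, r$qy, r$qz))
    })
    names(out) <- frames
    out
  })
  list(time = times, frames = frames, orientations = orientations)
}

#' @rdname mapdyn-io
#' @param s,s_dot,s_ddot joint trajectory matrices (samples x joints).
#' @param joint_names character vector.
#' @export
write_joint_csv <- function(time, s, s_dot = NULL, s_ddot = NULL,
                            joint_names = NULL, path) {
  n <- ncol(s)
  if (is.null(joint_names)) joint_names <- paste0("j", seq_len(n))
  df <- data.frame(time = time)
  df[joint_names] <- s
  if (!is.null(s_dot)) df[paste0(joint_names, "_dot")] <- s_dot
  if (!is.null(s_ddot)) df[paste0(joint_names, "_ddot")] <- s_ddot
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname mapdyn-io
#' @export
read_joint_csv <- function(path) {
  df <- utils::read.csv(path)
  nm <- names(df)
  base <- nm[!grepl("^time$|_dot$|_ddot$", nm)]
  list(time = df$time,
       s = as.matrix(df[base]),
       s_dot = if (any(grepl("_dot$", nm)))
         as.matrix(df[paste0(base, "_dot")]) else NULL,
       s_ddot = if (any(grepl("_ddot$", nm)))
         as.matrix(df[paste0(base, "_ddot")]) else NULL,
       joint_names = base)
}

#' @rdname mapdyn-io
#' @param rf_fz,lf_fz vertical force series (N).
#' @export
write_forces_csv <- function(time, rf_fz, lf_fz, path) {
  utils::write.csv(data.frame(time = time, rf_fz = rf_fz, lf_fz = lf_fz),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname mapdyn-io
#' @export
read_forces_csv <- function(path) utils::read.csv(path)

#' @rdname mapdyn-io
#' @param samples calibration sample data frame (see
#'   \code{\link{estimate_sensor_position}}).
#' @export
write_calibration_csv <- function(samples, path) {
  utils::write.csv(samples, path, row.names = FALSE)
  invisible(path)
}

#' @rdname mapdyn-io
#' @export
read_calibration_csv <- function(path) utils::read.csv(path)

#' Read / write estimator configuration as JSON
#'
#' @param config a \code{\link{map_config}}.
#' @param path file path.
#' @export
write_map_config <- function(config, path) {
  writeLines(jsonlite::toJSON(unclass(config), digits = NA,
                              auto_unbox = TRUE, null = "null"), path)
  invisible(path)
}

#' @rdname write_map_config
#' @export
read_map_config <- function(path) {
  obj <- jsonlite::fromJSON(path)
  do.call(map_config, obj[!vapply(obj, is.null, TRUE)])
}
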