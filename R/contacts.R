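#' Self-tuned vertical-force threshold for contact classification
#'
#' The double-support threshold is the mean over samples of the summed
#' vertical ground-reaction forces of the two feet, times a scale factor.
#' With \code{scale = 1} this is the literal self-tuned rule; because the
#' mean of the summed forces is close to body weight, smaller scales give
#' a narrower double-support band and are exposed as a tuning knob.
#'
#' @param rf_fz,lf_fz vertical force time series of the right and left
#'   foot (N), equal length.
#' @param scale positive scale factor on the mean.
#' @return the threshold \code{T_fz} in newtons.
#' @export
compute_threshold <- function(rf_fz, lf_fz, scale = 1) {
  if (length(rf_fz) == 0L) stop("empty force series")
  stopifnot(length(rf_fz) == length(lf_fz), scale > 0,
            all(is.finite(rf_fz)), all(is.finite(lf_fz)))
  scale * mean(rf_fz + lf_fz)
}

#' Classify gait samples as double / right / left support
#'
#' Per sample: if the absolute difference of the two vertical forces is
#' within the threshold the sample is double support; otherwise the foot
#' with the larger vertical force is the single-support side.
#'
#' @param rf_fz,lf_fz vertical force time series (N).
#' @param threshold non-negative force threshold \code{T_fz} (N), e.g.
#'   from \code{\link{compute_threshold}}.
#' @return factor with levels \code{double}, \code{right}, \code{left},
#'   one label per sample.
#' @export
classify_contacts <- function(rf_fz, lf_fz, threshold) {
  stopifnot(length(rf_fz) == length(lf_fz), threshold >= 0)
  lab <- ifelse(abs(rf_fz - lf_fz) <= threshold, "double",
                ifelse(rf_fz > lf_fz, "right", "left"))
  factor(lab, levels = c("double", "right", "left"))
}

#' Optional minimum-duration filter for contact labels
#'
#' Removes label runs shorter than \code{min_samples} by merging them into
#' the preceding run.  Off by default in the pipeline (the offline
#' classifier has no hysteresis).
#'
#' @param labels factor from \code{\link{classify_contacts}}.
#' @param min_samples minimum run length to keep.
#' @return relabelled factor.
#' @export
debounce_contacts <- function(labels, min_samples = 1L) {
  if (min_samples <= 1L) return(labels)
  r <- rle(as.character(labels))
  for (k in seq_along(r$lengths)[-1L]) {
    if (r$lengths[k] < min_samples) r$values[k] <- r$values[k - 1L]
  }
  factor(inverse.rle(r), levels = levels(labels))
}
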