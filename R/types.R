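# Domain containers shared across the pipeline. Plain S3 lists: the data
# are small (a few hundred frames, 17 landmarks) and the field's signal
# packages use the same idiom.

.coco <- c("nose", "left_eye", "right_eye", "left_ear", "right_ear",
           "left_shoulder", "right_shoulder", "left_elbow", "right_elbow",
           "left_wrist", "right_wrist", "left_hip", "right_hip",
           "left_knee", "right_knee", "left_ankle", "right_ankle")

#' COCO 17-landmark names in canonical order
#'
#' The keypoint order emitted by standard 2D/3D human pose estimators:
#' nose, eyes, ears, shoulders, elbows, wrists, hips, knees, ankles
#' (left before right within each pair).
#'
#' @return Character vector of length 17.
#' @export
coco_keypoints <- function() .coco

coco_index <- function(name) {
  i <- match(name, .coco)
  if (anyNA(i)) pk_stop(sprintf("unknown keypoint name: %s",
                                paste(name[is.na(i)], collapse = ", ")),
                        "pendknee_parameter_error")
  i
}

leg_indices <- function(side) {
  side <- match.arg(side, c("left", "right"))
  coco_index(paste0(side, c("_hip", "_knee", "_ankle")))
}

#' Construct a keypoint trajectory
#'
#' The raw input of the pipeline: per-frame coordinates for the 17 COCO
#' landmarks, in pixels (2D, with per-keypoint confidences) or consistent
#' length units (3D, no confidences).
#'
#' @param coords Numeric array `frames x 17 x dims`.
#' @param fps Frames per second (> 0, default 30).
#' @param confidence Optional `frames x 17` matrix of confidences in
#'   \[0, 1\] (2D only).
#' @param source_tag Free-text provenance tag, e.g. `"2d-pose"`.
#' @return An object of class `keypoint_trajectory` with fields `coords`,
#'   `confidence`, `fps`, `dims`, `n_frames`, `source_tag`.
#' @export
keypoint_trajectory <- function(coords, fps = 30,
                                confidence = NULL, source_tag = "") {
  d <- dim(coords)
  if (length(d) != 3 || d[2] != 17L || !(d[3] %in% c(2L, 3L))) {
    pk_stop("coords must be a frames x 17 x {2,3} numeric array",
            "pendknee_dialect_error")
  }
  if (!all(is.finite(coords))) {
    pk_stop("keypoint coordinates must all be finite",
            "pendknee_dialect_error")
  }
  if (!is.numeric(fps) || length(fps) != 1 || fps <= 0) {
    pk_stop("fps must be a single positive number",
            "pendknee_parameter_error")
  }
  if (!is.null(confidence)) {
    if (d[3] != 2L) {
      pk_stop("confidences are only defined for 2D trajectories",
              "pendknee_dialect_error")
    }
    if (!is.matrix(confidence) || !all(dim(confidence) == d[1:2])) {
      pk_stop("confidence must be a frames x 17 matrix",
              "pendknee_dialect_error")
    }
    if (any(confidence < 0 | confidence > 1, na.rm = TRUE)) {
      pk_stop("confidences must lie in [0, 1]", "pendknee_dialect_error")
    }
  }
  dimnames(coords) <- list(NULL, .coco, c("x", "y", "z")[seq_len(d[3])])
  structure(list(coords = coords, confidence = confidence, fps = fps,
                 dims = d[3], n_frames = d[1], source_tag = source_tag),
            class = "keypoint_trajectory")
}

#' @export
print.keypoint_trajectory <- function(x, ...) {
  cat(sprintf("<keypoint_trajectory> %d frames, %dD, %g fps%s\n",
              x$n_frames, x$dims, x$fps,
              if (nzchar(x$source_tag)) paste0(" [", x$source_tag, "]")
              else ""))
  invisible(x)
}

#' Construct a knee-angle time series
#'
#' The common currency between measurement devices: a uniformly sampled
#' knee flexion angle trace in degrees, 0 at full extension (collinear
#' thigh and shank), increasing with flexion.
#'
#' @param angles Numeric vector of angles in degrees, all in \[0, 180\].
#' @param fps Sampling rate in frames per second.
#' @param side `"left"`, `"right"` or `NA`.
#' @param device Measurement channel, e.g. `"goniometer"`, `"pose2d"`,
#'   `"pose3d"`, `"synthetic"`.
#' @param smoothed Logical: has the trace been smoothed?
#' @return Object of class `angle_trace`.
#' @export
angle_trace <- function(angles, fps, side = NA_character_,
                        device = NA_character_, smoothed = FALSE) {
  if (!is.numeric(angles) || length(angles) < 10) {
    pk_stop("an angle trace needs at least 10 samples",
            "pendknee_parameter_error")
  }
  if (!all(is.finite(angles))) {
    pk_stop("angle trace contains non-finite values",
            "pendknee_parameter_error")
  }
  if (any(angles < -1e-9 | angles > 180 + 1e-9)) {
    pk_stop("knee angles must lie in [0, 180] degrees",
            "pendknee_parameter_error")
  }
  if (!is.numeric(fps) || length(fps) != 1 || fps <= 0) {
    pk_stop("fps must be a single positive number",
            "pendknee_parameter_error")
  }
  structure(list(angles = pmin(pmax(as.numeric(angles), 0), 180),
                 fps = fps, side = side, device = device,
                 smoothed = isTRUE(smoothed)),
            class = "angle_trace")
}

#' @export
print.angle_trace <- function(x, ...) {
  cat(sprintf(
    "<angle_trace> %d samples @ %g fps (%.2f s), device=%s, %s\n",
    length(x$angles), x$fps, length(x$angles) / x$fps,
    x$device, if (x$smoothed) "smoothed" else "raw"))
  cat(sprintf("  range [%.1f, %.1f] deg\n",
              min(x$angles), max(x$angles)))
  invisible(x)
}

#' @export
as.data.frame.angle_trace <- function(x, ...) {
  data.frame(time_s = (seq_along(x$angles) - 1) / x$fps,
             angle_deg = x$angles)
}

trace_times <- function(trace) (seq_along(trace$angles) - 1) / trace$fps
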