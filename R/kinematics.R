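# Sagittal knee flexion angle from keypoints.
#
# 2D: theta = acos(u.v / |u||v|) with u = hip->knee, v = knee->ankle,
# evaluated directly in image coordinates (the angle is invariant to the
# y-down image convention, to translation and to uniform scaling).
#
# 3D: the sagittal plane is spanned by two body-midline vectors; its unit
# normal n removes the out-of-plane (mediolateral) component of each
# segment vector before the same arccos formula is applied to the in-plane
# parts uh = u - (u.n)n, vh = v - (v.n)n.

deg <- function(rad) rad * 180 / pi

# angle between row vectors of two matrices, degrees in [0, 180]; the
# cosine is clamped to [-1, 1] so collinear frames cannot raise spurious
# domain errors from floating-point overshoot
angle_rows <- function(u, v, context = "knee_angle") {
  nu <- sqrt(rowSums(u^2))
  nv <- sqrt(rowSums(v^2))
  tol <- 1e-12
  bad <- which(nu < tol | nv < tol)
  if (length(bad) > 0) {
    pk_stop(sprintf(
      "%s: zero-length segment vector (coincident keypoints) at frame %d",
      context, bad[1]), "pendknee_degenerate_error",
      data = list(frames = bad))
  }
  cosang <- pmin(pmax(rowSums(u * v) / (nu * nv), -1), 1)
  deg(acos(cosang))
}

# frames whose lower-limb keypoints fall below the confidence gate get NA
# angles, filled by linear interpolation so the grid stays uniform for the
# smoother (edge gaps extended from the nearest measured frame)
fill_flagged <- function(ang, flagged) {
  if (!any(flagged)) return(list(angles = ang, n_interpolated = 0L))
  if (all(flagged)) {
    pk_stop("every frame fell below the confidence gate",
            "pendknee_degenerate_error")
  }
  ang[flagged] <- NA_real_
  idx <- seq_along(ang)
  ang <- stats::approx(idx[!flagged], ang[!flagged], xout = idx,
                       rule = 2)$y
  list(angles = ang, n_interpolated = sum(flagged))
}

#' Knee flexion angle from a 2D keypoint trajectory
#'
#' Per-frame angle between the hip-to-knee and knee-to-ankle vectors of the
#' chosen limb, in degrees with 0 at full extension. Frames in which any of
#' the limb's three keypoints has confidence below
#' `config$conf.min_confidence` are treated as missing and filled by linear
#' interpolation (count available via `attr(, "n_interpolated")`).
#'
#' @param traj A 2D [keypoint_trajectory()].
#' @param side `"left"` or `"right"`.
#' @param config A [run_config()].
#' @return An [angle_trace()], unsmoothed, device `"pose2d"`.
#' @export
knee_angle_2d <- function(traj, side = c("right", "left"),
                          config = run_config()) {
  stopifnot(inherits(traj, "keypoint_trajectory"))
  side <- match.arg(side)
  if (traj$dims != 2) {
    pk_stop("knee_angle_2d requires a 2D trajectory",
            "pendknee_dialect_error")
  }
  idx <- leg_indices(side)
  co <- traj$coords
  u <- co[, idx[2], , drop = TRUE] - co[, idx[1], , drop = TRUE]
  v <- co[, idx[3], , drop = TRUE] - co[, idx[2], , drop = TRUE]
  if (is.null(dim(u))) { u <- matrix(u, 1); v <- matrix(v, 1) }

  flagged <- rep(FALSE, traj$n_frames)
  if (!is.null(traj$confidence)) {
    flagged <- apply(traj$confidence[, idx, drop = FALSE] <
                       config$conf.min_confidence, 1, any)
  }
  # degenerate geometry is only an error on frames that pass the gate;
  # gated frames are interpolated anyway
  nu <- sqrt(rowSums(u^2)); nv <- sqrt(rowSums(v^2))
  degen <- (nu < 1e-12 | nv < 1e-12)
  ok <- !flagged
  if (any(degen & ok)) {
    pk_stop(sprintf(
      "knee_angle_2d: zero-length segment vector (coincident keypoints) at frame %d",
      which(degen & ok)[1]), "pendknee_degenerate_error",
      data = list(frames = which(degen & ok)))
  }
  ang <- rep(NA_real_, traj$n_frames)
  ang[ok] <- angle_rows(u[ok, , drop = FALSE], v[ok, , drop = FALSE],
                        "knee_angle_2d")
  filled <- fill_flagged(ang, flagged)
  out <- angle_trace(filled$angles, fps = traj$fps, side = side,
                     device = "pose2d", smoothed = FALSE)
  attr(out, "n_interpolated") <- filled$n_interpolated
  out
}

# cross product of 3-vectors (rows)
cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' Sagittal-plane normal from two spanning vectors
#'
#' Raw geometry behind [sagittal_plane()]: the unit normal
#' `n = um x vm / |um x vm|` of the plane spanned by two midline vectors.
#'
#' @param um,vm Numeric length-3 vectors (or n x 3 matrices) spanning the
#'   sagittal plane.
#' @return Unit normal(s), same shape as the inputs.
#' @export
plane_normal <- function(um, vm) {
  if (is.null(dim(um))) um <- matrix(um, 1)
  if (is.null(dim(vm))) vm <- matrix(vm, 1)
  n <- cross3(um, vm)
  nn <- sqrt(rowSums(n^2))
  scale <- sqrt(rowSums(um^2)) * sqrt(rowSums(vm^2))
  bad <- which(nn < 1e-9 * pmax(scale, 1e-300))
  if (length(bad) > 0) {
    pk_stop(sprintf(
      "degenerate sagittal plane (collinear midline vectors) at frame %d",
      bad[1]), "pendknee_degenerate_error", data = list(frames = bad))
  }
  out <- n / nn
  if (nrow(out) == 1) drop(out) else out
}

midline_vectors <- function(traj, config) {
  co <- traj$coords
  mid_sh <- (co[, coco_index("left_shoulder"), ] +
               co[, coco_index("right_shoulder"), ]) / 2
  mid_hip <- (co[, coco_index("left_hip"), ] +
                co[, coco_index("right_hip"), ]) / 2
  if (is.null(dim(mid_sh))) { mid_sh <- matrix(mid_sh, 1)
                              mid_hip <- matrix(mid_hip, 1) }
  um <- mid_hip - mid_sh                      # longitudinal midline
  vm <- switch(config$plane.midline,
    nose = co[, coco_index("nose"), , drop = TRUE] - mid_hip,
    hip_axis = co[, coco_index("right_hip"), , drop = TRUE] -
               co[, coco_index("left_hip"), , drop = TRUE])
  if (is.null(dim(vm))) vm <- matrix(vm, 1)
  list(um = um, vm = vm)
}

#' Per-frame sagittal plane of a 3D trajectory
#'
#' Estimates the sagittal-plane unit normal from body-midline landmarks.
#' With the default `plane.midline = "nose"` the spanning vectors are
#' mid-shoulder to mid-hip (longitudinal) and mid-hip to nose; both lie in
#' the midsagittal plane, so their cross product is the mediolateral
#' normal. `plane.mode = "averaged"` replaces the per-frame normals by
#' their normalized mean.
#'
#' @param traj A 3D `keypoint_trajectory`.
#' @param config A [run_config()].
#' @return List with `um`, `vm` (n x 3) and `n` (n x 3 unit normals).
#' @export
sagittal_plane <- function(traj, config = run_config()) {
  stopifnot(inherits(traj, "keypoint_trajectory"))
  if (traj$dims != 3) {
    pk_stop("sagittal_plane requires a 3D trajectory",
            "pendknee_dialect_error")
  }
  mv <- midline_vectors(traj, config)
  n <- plane_normal(mv$um, mv$vm)
  if (is.null(dim(n))) n <- matrix(n, 1)
  if (config$plane.mode == "averaged") {
    # align signs before averaging so antipodal normals do not cancel
    ref <- n[1, ]
    sgn <- sign(n %*% ref)
    sgn[sgn == 0] <- 1
    m <- colMeans(n * as.numeric(sgn))
    m <- m / sqrt(sum(m^2))
    n <- matrix(m, nrow(n), 3, byrow = TRUE)
  }
  list(um = mv$um, vm = mv$vm, n = n)
}

project_out <- function(v, n) v - rowSums(v * n) * n

#' Knee flexion angle from a 3D keypoint trajectory
#'
#' Removes each segment vector's out-of-plane component with respect to the
#' per-frame sagittal plane and measures the angle between the in-plane
#' parts, same convention as [knee_angle_2d()]. A segment nearly
#' perpendicular to the sagittal plane (in-plane component below 1e-6 of
#' the segment length) is a degenerate-projection error.
#'
#' @inheritParams knee_angle_2d
#' @return An [angle_trace()], unsmoothed, device `"pose3d"`.
#' @export
knee_angle_3d <- function(traj, side = c("right", "left"),
                          config = run_config()) {
  stopifnot(inherits(traj, "keypoint_trajectory"))
  side <- match.arg(side)
  if (traj$dims != 3) {
    pk_stop("knee_angle_3d requires a 3D trajectory",
            "pendknee_dialect_error")
  }
  pl <- sagittal_plane(traj, config)
  idx <- leg_indices(side)
  co <- traj$coords
  u <- co[, idx[2], , drop = TRUE] - co[, idx[1], , drop = TRUE]
  v <- co[, idx[3], , drop = TRUE] - co[, idx[2], , drop = TRUE]
  if (is.null(dim(u))) { u <- matrix(u, 1); v <- matrix(v, 1) }
  uh <- project_out(u, pl$n)
  vh <- project_out(v, pl$n)
  rel <- function(h, full) sqrt(rowSums(h^2)) / pmax(sqrt(rowSums(full^2)),
                                                     1e-300)
  bad <- which(rel(uh, u) < 1e-6 | rel(vh, v) < 1e-6)
  if (length(bad) > 0) {
    pk_stop(sprintf(
      "segment perpendicular to the sagittal plane at frame %d", bad[1]),
      "pendknee_degenerate_error", data = list(frames = bad))
  }
  ang <- angle_rows(uh, vh, "knee_angle_3d")
  angle_trace(ang, fps = traj$fps, side = side, device = "pose3d",
              smoothed = FALSE)
}

#' Savitzky-Golay smoothing of an angle trace
#'
#' Third-order (by default) local polynomial least-squares smoothing, the
#' standard choice for pendulum traces because it preserves the peak and
#' trough amplitudes the landmark extraction depends on. Same-length
#' output; edge samples come from the filter's off-center polynomial fits,
#' so polynomials up to the filter order are reproduced exactly everywhere.
#'
#' @param trace An [angle_trace()].
#' @param window_frames Odd window length, `> polyorder`, at most the trace
#'   length. Defaults to the config value (11 frames).
#' @param polyorder Polynomial order, default 3.
#' @param config A [run_config()] supplying defaults.
#' @return The smoothed `angle_trace` (`smoothed = TRUE`).
#' @export
smooth_trace <- function(trace, window_frames = NULL, polyorder = NULL,
                         config = run_config()) {
  stopifnot(inherits(trace, "angle_trace"))
  w <- if (is.null(window_frames)) config$smoothing.window_frames
       else window_frames
  p <- if (is.null(polyorder)) config$smoothing.polyorder else polyorder
  if (w %% 2 == 0 || w < 5) {
    pk_stop("smoothing window must be an odd integer >= 5",
            "pendknee_parameter_error")
  }
  if (p >= w) {
    pk_stop("polynomial order must be smaller than the window",
            "pendknee_parameter_error")
  }
  if (w > length(trace$angles)) {
    pk_stop("smoothing window exceeds trace length",
            "pendknee_parameter_error")
  }
  sm <- signal::sgolayfilt(trace$angles, p = p, n = w)
  angle_trace(pmin(pmax(sm, 0), 180), fps = trace$fps, side = trace$side,
              device = trace$device, smoothed = TRUE)
}
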