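# Landmark extraction on the angle-time curve.
#
# Convention: angles are flexion-positive with 0 at full extension, so the
# leg's physical lowest point (maximal knee flexion) is a local MAXIMUM of
# the trace and the highest point (maximal extension) a local minimum.
# The release sample -- the global start at maximal extension -- is
# prepended to the extremum sequence as the initial extremum.
#
# Landmarks, with theta_start the release-frame angle, theta_rest the
# settled resting angle and e1, e2, e3 the first three interior extrema
# (flexion peak, extension trough, flexion peak):
#   A0 = |theta_start - theta_rest|   release-to-rest baseline
#   A1 = e1 - theta_start             first-swing excursion
#   A3 = |e2 - theta_rest|            second-swing offset from rest
#   A4 = |e3 - e2|                    second-swing cycle excursion
# and P1 = A1/A0, P2 = A3, P3 = A4/A3. No "A2" exists in this naming
# scheme; none is invented here.

#' Locate swing extrema on an angle trace
#'
#' Scans the (ideally smoothed) trace for local maxima and minima, takes
#' the first frame of any plateau for determinism, and prunes wiggles:
#' while two successive turning points (or a turning point and the trace
#' start/end) differ by less than `min_prominence_deg`, the offending
#' extremum pair (or edge extremum) is removed, preserving peak/trough
#' alternation. The release sample (frame 1) is prepended as the initial
#' extremum.
#'
#' @param trace An [angle_trace()]; length at least 10. Smoothing first is
#'   strongly recommended for measured data.
#' @param min_prominence_deg Minimum accepted excursion between successive
#'   extrema, degrees (default from `config`).
#' @param config A [run_config()].
#' @return A `data.frame` with columns `frame_index`, `angle`, `kind`
#'   (`"peak"`/`"trough"`); row 1 is the release sample.
#' @export
find_extrema <- function(trace, min_prominence_deg = NULL,
                         config = run_config()) {
  stopifnot(inherits(trace, "angle_trace"))
  thr <- if (is.null(min_prominence_deg)) config$extrema.min_prominence_deg
         else min_prominence_deg
  x <- trace$angles
  n <- length(x)
  s <- sign(diff(x))
  nz <- which(s != 0)
  if (length(nz) >= 2) {
    flips <- which(s[nz[-1]] != s[nz[-length(nz)]])
    idx <- nz[flips] + 1L          # first frame of the plateau/turn
    kind <- ifelse(s[nz[flips]] > 0, "peak", "trough")
  } else {
    idx <- integer(0)
    kind <- character(0)
  }

  # prominence pruning. Three moves, each preserving peak/trough
  # alternation, iterated to a fixed point:
  #  - drop a leading extremum that barely departs from the release value
  #    (a pre-swing wiggle);
  #  - truncate trailing extrema whose excursion from their predecessor is
  #    below threshold (the decayed tail: each swing is judged against the
  #    previous turning point, not against the settled trace end, so a
  #    small genuine second swing survives);
  #  - remove interior adjacent pairs closer than the threshold (noise
  #    wiggles riding on a swing).
  ang <- x[idx]
  drop_at <- function(at) {
    idx <<- idx[-at]; ang <<- ang[-at]; kind <<- kind[-at]
  }
  repeat {
    changed <- FALSE
    while (length(idx) > 0 && abs(ang[1] - x[1]) < thr) {
      drop_at(1); changed <- TRUE
    }
    repeat {
      m <- length(idx)
      if (m == 0) break
      prev <- if (m == 1) x[1] else ang[m - 1]
      if (abs(ang[m] - prev) < thr) { drop_at(m); changed <- TRUE }
      else break
    }
    if (length(idx) >= 2) {
      gaps <- abs(diff(ang))
      small <- which(gaps < thr)
      if (length(small) > 0) {
        g <- small[which.min(gaps[small])]
        drop_at(c(g, g + 1)); changed <- TRUE
      }
    }
    if (!changed) break
  }

  if (length(idx) == 0) {
    pk_stop(
      "no swing extrema beyond the release sample (overdamped or monotone trace)",
      "pendknee_overdamped_error")
  }
  data.frame(
    frame_index = c(1L, idx),
    angle = c(x[1], ang),
    kind = c(if (kind[1] == "peak") "trough" else "peak", kind),
    stringsAsFactors = FALSE)
}

#' Resting knee angle from the trace tail
#'
#' Mean angle over the final `tail_seconds` of the recording, where the
#' oscillation has decayed. If the tail variance exceeds 5 squared degrees
#' the trace may not have settled; a warning (class
#' `pendknee_unsettled_warning`) is raised and the value returned anyway.
#'
#' @param trace An [angle_trace()].
#' @param tail_seconds Averaging window length in seconds (default from
#'   `config`, 1.0 s).
#' @param config A [run_config()].
#' @return Resting angle in degrees, with attribute `settled`.
#' @export
resting_angle <- function(trace, tail_seconds = NULL,
                          config = run_config()) {
  stopifnot(inherits(trace, "angle_trace"))
  ts <- if (is.null(tail_seconds)) config$rest.tail_seconds else tail_seconds
  n_tail <- round(ts * trace$fps)
  n <- length(trace$angles)
  if (n_tail >= n) {
    pk_stop(sprintf(
      "trace (%.2f s) is not longer than the rest window (%.2f s)",
      n / trace$fps, ts), "pendknee_parameter_error")
  }
  tail_vals <- trace$angles[(n - n_tail + 1):n]
  settled <- stats::var(tail_vals) <= 5
  if (!settled) {
    pk_warn(sprintf(
      "rest window variance %.1f deg^2 > 5: trace may not have settled",
      stats::var(tail_vals)), "pendknee_unsettled_warning")
  }
  structure(mean(tail_vals), settled = settled)
}

#' Swing landmarks A0, A1, A3, A4
#'
#' Derives the four angular landmarks from the extremum sequence (see the
#' file-level convention note). Requires at least three interior extrema
#' in the order flexion peak, extension trough, flexion peak; traces too
#' damped to complete a second swing raise a typed overdamped-trace error
#' whose condition data carry the landmarks that could still be measured
#' (`A0`, and `A1` when a first peak exists), so study-level code can
#' count exclusions explicitly instead of receiving silent NAs.
#'
#' @param trace A smoothed [angle_trace()].
#' @param config A [run_config()].
#' @return Object of class `swing_landmarks`: list with `A0`, `A1`, `A3`,
#'   `A4`, `rest_angle`, `settled`, and the backing `extrema` table.
#' @export
swing_landmarks <- function(trace, config = run_config()) {
  stopifnot(inherits(trace, "angle_trace"))
  settled <- TRUE
  rest <- withCallingHandlers(
    resting_angle(trace, config = config),
    pendknee_unsettled_warning = function(w) {
      settled <<- FALSE
      invokeRestart("muffleWarning")
    })
  theta_start <- trace$angles[1]
  A0 <- abs(theta_start - as.numeric(rest))

  partial <- list(A0 = A0, A1 = NA_real_, A3 = NA_real_, A4 = NA_real_,
                  rest_angle = as.numeric(rest), settled = settled)
  ex <- tryCatch(find_extrema(trace, config = config),
                 pendknee_overdamped_error = function(e) NULL)
  if (is.null(ex)) {
    pk_stop("overdamped trace: no interior swing extrema; landmarks undefined",
            "pendknee_overdamped_error", data = list(partial = partial))
  }
  interior <- ex[-1, , drop = FALSE]
  if (nrow(interior) >= 1 && interior$kind[1] == "peak") {
    partial$A1 <- interior$angle[1] - theta_start
  }
  if (nrow(interior) < 3) {
    pk_stop(sprintf(
      "overdamped trace: %d interior extrema, need 3 for A3/A4",
      nrow(interior)), "pendknee_overdamped_error",
      data = list(partial = partial))
  }
  if (!identical(interior$kind[1:3], c("peak", "trough", "peak"))) {
    pk_stop(
      "unexpected extremum pattern: expected flexion peak, extension trough, flexion peak",
      "pendknee_overdamped_error", data = list(partial = partial))
  }
  e <- interior$angle[1:3]
  structure(list(A0 = A0,
                 A1 = e[1] - theta_start,
                 A3 = abs(e[2] - as.numeric(rest)),
                 A4 = abs(e[3] - e[2]),
                 rest_angle = as.numeric(rest),
                 settled = settled,
                 extrema = ex),
            class = "swing_landmarks")
}

#' @export
print.swing_landmarks <- function(x, ...) {
  cat(sprintf(
    "<swing_landmarks> A0=%.2f A1=%.2f A3=%.2f A4=%.2f (rest %.2f deg%s)\n",
    x$A0, x$A1, x$A3, x$A4, x$rest_angle,
    if (isTRUE(x$settled)) "" else ", unsettled tail"))
  invisible(x)
}

#' Pendulum parameters P1, P2, P3
#'
#' * P1 (normalized relaxation index) = A1 / A0 -- first-swing excursion
#'   normalized by the release-to-rest distance; lower with greater
#'   spasticity.
#' * P2 (first maximum of oscillation) = A3, in degrees.
#' * P3 (relaxation index at half swing) = A4 / A3 -- an energy-retention
#'   ratio of the second swing cycle.
#'
#' A zero A0 makes every parameter undefined (error). A zero A3 leaves P3
#' undefined (`NA` with `p3_defined = FALSE`) while P1 and P2 are still
#' returned.
#'
#' @param lm A [swing_landmarks()] object (or list with A0, A1, A3, A4).
#' @return Object of class `pendulum_parameters`: list with `P1`, `P2`,
#'   `P3`, `p3_defined`.
#' @export
pendulum_parameters <- function(lm) {
  eps <- 1e-9
  if (!is.finite(lm$A0) || lm$A0 <= eps) {
    pk_stop("A0 = 0: pendulum parameters undefined",
            "pendknee_parameter_error")
  }
  p3_def <- is.finite(lm$A3) && lm$A3 > eps && is.finite(lm$A4)
  structure(list(
    P1 = lm$A1 / lm$A0,
    P2 = lm$A3,
    P3 = if (p3_def) lm$A4 / lm$A3 else NA_real_,
    p3_defined = p3_def),
    class = "pendulum_parameters")
}

#' @export
print.pendulum_parameters <- function(x, ...) {
  cat(sprintf("<pendulum_parameters> P1=%.3f P2=%.2f deg P3=%s\n",
              x$P1, x$P2,
              if (x$p3_defined) sprintf("%.3f", x$P3) else "undefined"))
  invisible(x)
}
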