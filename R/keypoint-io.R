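# File dialects. 2D keypoints use the AlphaPose-style JSON export: an array
# of per-frame objects {image_id, keypoints = [x1, y1, s1, ..., x17, y17,
# s17], score, idx}. 3D keypoints are either a JSON array (frames x 17 x 3)
# or a long CSV (frame, kp, x, y, z). Angle traces are two-column CSVs.
#
# Image coordinates are y-down (image convention). The knee-angle
# computation is invariant to that choice, so no flip is applied anywhere.

#' Read a 2D keypoint file (AlphaPose-style JSON)
#'
#' Parses a per-frame JSON export from a 2D pose estimator into a
#' [keypoint_trajectory()]. Frames are sorted by the numeric part of their
#' `image_id` (falling back to lexicographic order). The reader assumes a
#' single tracked person: two records sharing one `image_id` are a hard
#' error, because the pendulum-test protocol guarantees one subject in
#' frame and any heuristic pick would be silent data corruption.
#'
#' @param path Path to the JSON file.
#' @param fps Frames per second of the recording (default 30).
#' @return A `keypoint_trajectory` with `dims = 2` and confidences.
#' @export
read_keypoints_2d <- function(path, fps = 30) {
  recs <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) {
      pk_stop(sprintf("malformed JSON in '%s': %s", path,
                      conditionMessage(e)),
              "pendknee_parse_error")
    })
  if (length(recs) == 0) {
    pk_stop(sprintf("'%s' contains no frame records", path),
            "pendknee_dialect_error")
  }
  ids <- vapply(recs, function(r) {
    if (is.null(r$image_id)) {
      pk_stop(sprintf("frame record without image_id in '%s'", path),
              "pendknee_dialect_error")
    }
    as.character(r$image_id)
  }, character(1))
  if (anyDuplicated(ids)) {
    dup <- ids[duplicated(ids)][1]
    pk_stop(sprintf(
      paste0("multiple person records for frame '%s' in '%s'; this reader ",
             "is single-subject -- pre-filter the export to one tracked ",
             "person id"), dup, path),
      "pendknee_dialect_error")
  }
  num <- suppressWarnings(as.numeric(sub("\\D.*$", "", ids)))
  ord <- if (anyNA(num)) order(ids) else order(num)
  recs <- recs[ord]

  n <- length(recs)
  coords <- array(NA_real_, c(n, 17, 2))
  conf <- matrix(NA_real_, n, 17)
  for (i in seq_len(n)) {
    kp <- unlist(recs[[i]]$keypoints)
    if (length(kp) != 51 || !is.numeric(kp)) {
      pk_stop(sprintf(
        "frame '%s' in '%s': keypoint array has length %d, expected 51",
        ids[ord][i], path, length(kp)),
        "pendknee_dialect_error")
    }
    m <- matrix(kp, ncol = 3, byrow = TRUE)
    coords[i, , ] <- m[, 1:2]
    conf[i, ] <- m[, 3]
  }
  keypoint_trajectory(coords, fps = fps, confidence = conf,
                      source_tag = "2d-pose")
}

#' Write a 2D keypoint trajectory as AlphaPose-style JSON
#'
#' Inverse of [read_keypoints_2d()]; coordinates survive the round trip
#' bit-for-bit (17 significant digits).
#'
#' @param traj A 2D `keypoint_trajectory`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_keypoints_2d <- function(traj, path) {
  stopifnot(inherits(traj, "keypoint_trajectory"))
  if (traj$dims != 2) {
    pk_stop("write_keypoints_2d requires a 2D trajectory",
            "pendknee_dialect_error")
  }
  conf <- traj$confidence
  if (is.null(conf)) conf <- matrix(1, traj$n_frames, 17)
  recs <- lapply(seq_len(traj$n_frames), function(i) {
    kp <- as.numeric(t(cbind(traj$coords[i, , ], conf[i, ])))
    list(image_id = sprintf("%06d.jpg", i - 1),
         keypoints = kp,
         score = mean(conf[i, ]),
         idx = 0L)
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Read a 3D keypoint file
#'
#' Accepts either a JSON array of shape frames x 17 x 3 or a long CSV with
#' columns `frame, kp, x, y, z` (one row per frame-keypoint pair; `frame`
#' and `kp` 1-based). Every frame must carry all 17 keypoints.
#'
#' @param path Path to the file; format chosen by extension (`.json` vs
#'   `.csv`).
#' @param fps Frames per second (default 30).
#' @return A `keypoint_trajectory` with `dims = 3` and no confidences.
#' @export
read_keypoints_3d <- function(path, fps = 30) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    arr <- tryCatch(jsonlite::fromJSON(path),
                    error = function(e) {
                      pk_stop(sprintf("malformed JSON in '%s': %s", path,
                                      conditionMessage(e)),
                              "pendknee_parse_error")
                    })
    if (!is.array(arr) || length(dim(arr)) != 3 ||
        dim(arr)[2] != 17 || dim(arr)[3] != 3) {
      pk_stop(sprintf("'%s' is not a frames x 17 x 3 array", path),
              "pendknee_dialect_error")
    }
    coords <- arr
  } else {
    df <- utils::read.csv(path)
    need <- c("frame", "kp", "x", "y", "z")
    if (!all(need %in% names(df))) {
      pk_stop(sprintf("'%s' must have columns %s", path,
                      paste(need, collapse = ", ")),
              "pendknee_dialect_error")
    }
    frames <- sort(unique(df$frame))
    n <- length(frames)
    coords <- array(NA_real_, c(n, 17, 3))
    for (i in seq_len(n)) {
      sub <- df[df$frame == frames[i], ]
      miss <- setdiff(1:17, sub$kp)
      if (length(miss) > 0) {
        pk_stop(sprintf("frame %s in '%s' is missing keypoint(s) %s",
                        frames[i], path, paste(miss, collapse = ", ")),
                "pendknee_dialect_error")
      }
      sub <- sub[order(sub$kp), ]
      coords[i, , ] <- as.matrix(sub[, c("x", "y", "z")])
    }
  }
  if (!all(is.finite(coords))) {
    bad <- which(apply(coords, 1, function(f) !all(is.finite(f))))
    pk_stop(sprintf("non-finite coordinates in '%s' (frame(s) %s)", path,
                    paste(utils::head(bad, 5), collapse = ", ")),
            "pendknee_dialect_error")
  }
  keypoint_trajectory(coords, fps = fps, source_tag = "3d-pose")
}

#' Write a 3D keypoint trajectory as long CSV
#'
#' Columns `frame, kp, x, y, z`, 1-based indices, full-precision
#' coordinates (bit-for-bit round trip through [read_keypoints_3d()]).
#'
#' @param traj A 3D `keypoint_trajectory`.
#' @param path Output path (`.csv`).
#' @return `path`, invisibly.
#' @export
write_keypoints_3d <- function(traj, path) {
  stopifnot(inherits(traj, "keypoint_trajectory"))
  if (traj$dims != 3) {
    pk_stop("write_keypoints_3d requires a 3D trajectory",
            "pendknee_dialect_error")
  }
  n <- traj$n_frames
  df <- data.frame(
    frame = rep(seq_len(n), each = 17),
    kp = rep(1:17, n),
    x = sprintf("%.17g", as.numeric(t(traj$coords[, , 1]))),
    y = sprintf("%.17g", as.numeric(t(traj$coords[, , 2]))),
    z = sprintf("%.17g", as.numeric(t(traj$coords[, , 3]))))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an angle-trace CSV
#'
#' Reads a two-column export (`time_s`, `angle_deg`) such as an electronic
#' goniometer recording. The sampling rate is inferred from the median time
#' step. If timestamps jitter by more than 1% of that step, the trace is
#' resampled onto a uniform grid by linear interpolation and a notice is
#' emitted; mild jitter below the threshold is accepted as-is.
#'
#' @param path CSV path with header columns `time_s` (strictly increasing)
#'   and `angle_deg`.
#' @param convention `"extension_zero"` (default) if the export already uses
#'   0 deg = straight leg; `"extension_180"` for the clinical
#'   180-at-extension convention, converted to extension-zero on read.
#' @param side,device Metadata carried into the returned trace.
#' @return An [angle_trace()].
#' @export
read_angle_csv <- function(path, convention = c("extension_zero",
                                                "extension_180"),
                           side = NA_character_, device = "goniometer") {
  convention <- match.arg(convention)
  df <- utils::read.csv(path)
  if (!all(c("time_s", "angle_deg") %in% names(df))) {
    pk_stop(sprintf("'%s' must have columns time_s, angle_deg", path),
            "pendknee_dialect_error")
  }
  t <- df$time_s
  a <- df$angle_deg
  if (length(t) < 10) {
    pk_stop(sprintf(
      "'%s': %d samples; traces shorter than 10 samples are too short to analyze",
      path, length(t)), "pendknee_parameter_error")
  }
  dt <- diff(t)
  if (any(dt <= 0)) {
    pk_stop(sprintf(
      "'%s': time column is not strictly increasing (first violation at row %d)",
      path, which(dt <= 0)[1] + 1L), "pendknee_parse_error")
  }
  step <- stats::median(dt)
  if (max(abs(dt - step)) > 0.01 * step) {
    message(sprintf(
      "read_angle_csv: timestamp jitter > 1%% in '%s'; resampling to a %.4f s grid",
      path, step))
    grid <- seq(t[1], t[length(t)], by = step)
    a <- stats::approx(t, a, xout = grid, rule = 2)$y
  }
  if (convention == "extension_180") a <- 180 - a
  angle_trace(a, fps = 1 / step, side = side, device = device,
              smoothed = FALSE)
}

#' Write an angle trace as CSV
#'
#' @param trace An `angle_trace`.
#' @param path Output path; columns `time_s`, `angle_deg`.
#' @return `path`, invisibly.
#' @export
write_angle_csv <- function(trace, path) {
  stopifnot(inherits(trace, "angle_trace"))
  df <- data.frame(time_s = sprintf("%.17g", trace_times(trace)),
                   angle_deg = sprintf("%.17g", trace$angles))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.mas_levels <- c(`0` = 0, `1` = 1, `1+` = 1.5, `1.5` = 1.5,
                 `2` = 2, `3` = 3, `4` = 4)

parse_mas <- function(tok, column) {
  tok <- trimws(as.character(tok))
  v <- .mas_levels[tok]
  if (anyNA(v)) {
    pk_stop(sprintf("unknown MAS token '%s' in column %s (allowed: %s)",
                    tok[is.na(v)][1], column,
                    paste(names(.mas_levels), collapse = ", ")),
            "pendknee_parse_error")
  }
  unname(v)
}

#' Read a trial-metadata table
#'
#' Validates the study-layout CSV: one row per trial per device, columns
#' `subject_id, limb, affected, mas_flexor, mas_extensor, device,
#' camera_view, trial_index` and optionally `path` (per-trial input file).
#' The Modified Ashworth Scale token `"1+"` is stored as the ordinal level
#' 1.5, strictly between 1 and 2.
#'
#' @param path CSV path.
#' @return A validated `data.frame` with numeric MAS columns.
#' @export
read_trial_table <- function(path) {
  df <- utils::read.csv(path, colClasses = c(subject_id = "character"))
  need <- c("subject_id", "limb", "affected", "mas_flexor", "mas_extensor",
            "device", "camera_view", "trial_index")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    pk_stop(sprintf("trial table '%s' lacks column(s): %s", path,
                    paste(miss, collapse = ", ")),
            "pendknee_dialect_error")
  }
  if (!all(df$limb %in% c("left", "right"))) {
    pk_stop("limb must be 'left' or 'right'", "pendknee_parse_error")
  }
  df$affected <- as.logical(df$affected)
  if (anyNA(df$affected)) {
    pk_stop("affected must be TRUE/FALSE", "pendknee_parse_error")
  }
  df$mas_flexor <- parse_mas(df$mas_flexor, "mas_flexor")
  df$mas_extensor <- parse_mas(df$mas_extensor, "mas_extensor")
  if (!all(df$device %in% c("goniometer", "pose2d", "pose3d"))) {
    pk_stop("device must be goniometer, pose2d or pose3d",
            "pendknee_parse_error")
  }
  if (!all(as.character(df$camera_view) %in% c("45", "90", "none"))) {
    pk_stop("camera_view must be 45, 90 or none", "pendknee_parse_error")
  }
  df$camera_view <- as.character(df$camera_view)
  if (!all(df$trial_index %in% 1:5)) {
    pk_stop("trial_index must lie in 1..5", "pendknee_parse_error")
  }
  key <- paste(df$subject_id, df$limb, df$device, df$trial_index, sep = "|")
  if (anyDuplicated(key)) {
    pk_stop(sprintf("duplicate trial key (subject, limb, device, trial): %s",
                    key[duplicated(key)][1]),
            "pendknee_parse_error")
  }
  df
}
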