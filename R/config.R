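#' Analysis configuration
#'
#' Builds the validated configuration list consumed by the kinematics and
#' swing-analysis operations. Every key has a default chosen for 30 fps
#' pendulum-test recordings; unknown keys are rejected so that typos in a
#' config file fail loudly rather than silently falling back to defaults.
#'
#' Keys and defaults:
#' \describe{
#'   \item{smoothing.window_frames}{Savitzky-Golay window length in frames,
#'     odd, default 11 (about 0.37 s at 30 fps): wide enough to suppress
#'     keypoint jitter, narrow enough to preserve ~1 Hz swing peaks.}
#'   \item{smoothing.polyorder}{Polynomial order of the smoother, default 3.}
#'   \item{extrema.min_prominence_deg}{Minimum excursion (degrees) between
#'     successive swing extrema for both to be kept, default 1.0: above
#'     numerical ripple, below post-smoothing pose jitter.}
#'   \item{rest.tail_seconds}{Length of the terminal window averaged to
#'     estimate the resting knee angle, default 1.0 s.}
#'   \item{conf.min_confidence}{2D keypoint confidence below which a frame's
#'     angle is treated as missing and filled by linear interpolation,
#'     default 0.3.}
#'   \item{plane.mode}{Sagittal-plane estimation: `"per_frame"` (default) or
#'     `"averaged"` (single normal averaged over frames, more noise-robust
#'     when the pelvis is static).}
#'   \item{plane.midline}{Midline vectors spanning the sagittal plane:
#'     `"nose"` (default; mid-shoulder to mid-hip crossed with mid-hip to
#'     nose, both in the midsagittal plane, so the normal is mediolateral)
#'     or `"hip_axis"` (mid-shoulder to mid-hip crossed with the hip-to-hip
#'     axis; kept for sensitivity analysis).}
#'   \item{angle.convention}{`"extension_zero"` (default; 0 deg = straight
#'     leg, increasing with flexion) or `"extension_180"` for goniometer
#'     exports using the clinical 180-at-extension convention, converted on
#'     read.}
#' }
#'
#' @param ... Named overrides of the defaults above.
#' @return A named list of class `pendknee_config`.
#' @examples
#' cfg <- run_config(smoothing.window_frames = 15)
#' cfg$smoothing.window_frames
#' @export
run_config <- function(...) {
  defaults <- list(
    smoothing.window_frames = 11L,
    smoothing.polyorder = 3L,
    extrema.min_prominence_deg = 1.0,
    rest.tail_seconds = 1.0,
    conf.min_confidence = 0.3,
    plane.mode = "per_frame",
    plane.midline = "nose",
    angle.convention = "extension_zero"
  )
  override <- list(...)
  if (length(override) > 0 &&
      (is.null(names(override)) || any(names(override) == ""))) {
    pk_stop("configuration overrides must be named",
            "pendknee_parameter_error")
  }
  unknown <- setdiff(names(override), names(defaults))
  if (length(unknown) > 0) {
    pk_stop(sprintf("unknown configuration key(s): %s",
                    paste(unknown, collapse = ", ")),
            "pendknee_parameter_error")
  }
  cfg <- utils::modifyList(defaults, override)
  validate_config(cfg)
  structure(cfg, class = "pendknee_config")
}

validate_config <- function(cfg) {
  w <- cfg$smoothing.window_frames
  p <- cfg$smoothing.polyorder
  if (!is.numeric(w) || length(w) != 1 || w < 5 || w %% 2 == 0) {
    pk_stop("smoothing.window_frames must be a single odd integer >= 5",
            "pendknee_parameter_error")
  }
  if (!is.numeric(p) || length(p) != 1 || p < 1 || p >= w) {
    pk_stop("smoothing.polyorder must be >= 1 and < window length",
            "pendknee_parameter_error")
  }
  if (!is.numeric(cfg$extrema.min_prominence_deg) ||
      cfg$extrema.min_prominence_deg < 0) {
    pk_stop("extrema.min_prominence_deg must be >= 0",
            "pendknee_parameter_error")
  }
  if (!is.numeric(cfg$rest.tail_seconds) || cfg$rest.tail_seconds <= 0) {
    pk_stop("rest.tail_seconds must be > 0", "pendknee_parameter_error")
  }
  if (!is.numeric(cfg$conf.min_confidence) ||
      cfg$conf.min_confidence < 0 || cfg$conf.min_confidence > 1) {
    pk_stop("conf.min_confidence must lie in [0, 1]",
            "pendknee_parameter_error")
  }
  if (!cfg$plane.mode %in% c("per_frame", "averaged")) {
    pk_stop("plane.mode must be 'per_frame' or 'averaged'",
            "pendknee_parameter_error")
  }
  if (!cfg$plane.midline %in% c("nose", "hip_axis")) {
    pk_stop("plane.midline must be 'nose' or 'hip_axis'",
            "pendknee_parameter_error")
  }
  if (!cfg$angle.convention %in% c("extension_zero", "extension_180")) {
    pk_stop("angle.convention must be 'extension_zero' or 'extension_180'",
            "pendknee_parameter_error")
  }
  invisible(cfg)
}

#' Read a YAML configuration file
#'
#' Loads a YAML file whose top-level keys are the [run_config()] keys and
#' merges it over the defaults. Unknown keys are rejected.
#'
#' @param path Path to a YAML file.
#' @return A `pendknee_config` list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) {
    pk_stop(sprintf("config file not found: %s", path),
            "pendknee_parse_error")
  }
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  do.call(run_config, vals)
}
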