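# Synthetic pendulum-test data with known ground truth.
#
# The knee is modelled as a linear damped oscillator around its resting
# angle: theta(t) = theta_rest + (theta_release - theta_rest) * h(t) with,
# for damping ratio zeta < 1,
#   h(t) = exp(-zeta w t) [cos(wd t) + zeta/sqrt(1-zeta^2) sin(wd t)],
#   wd = w sqrt(1 - zeta^2),
# released from rest velocity at full extension. Successive amplitude
# extrema (relative to rest) decay by r = exp(-pi zeta / sqrt(1-zeta^2))
# per half cycle and occur at t_k = k pi / wd, which yields closed-form
# swing landmarks and therefore exact oracles for the analysis pipeline:
#   A0 = A, A1 = A(1+r), A3 = A r^2, A4 = A r^2 (1+r),
#   P1 = P3 = 1 + r, P2 = A r^2,    A = |theta_release - theta_rest|.
# Critically damped and overdamped regimes use the matching closed forms
# and produce monotone settling traces (no landmarks, by design).

# run code with a locally seeded RNG, restoring global RNG state after
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Damped-pendulum knee model
#'
#' @param omega_n Natural angular frequency, rad/s (> 0; a relaxed adult
#'   shank swings near 1 Hz, so ~5-6 rad/s is typical).
#' @param zeta Damping ratio (>= 0; spasticity increases damping).
#' @param theta_rest Resting knee angle, degrees.
#' @param theta_release Release angle, degrees (0 = full extension).
#' @param duration_s Recording length, seconds.
#' @param fps Sampling rate, frames per second.
#' @return Object of class `pendulum_model`.
#' @export
pendulum_model <- function(omega_n = 5.5, zeta = 0.2, theta_rest = 70,
                           theta_release = 0, duration_s = 12, fps = 30) {
  if (omega_n <= 0) pk_stop("omega_n must be > 0",
                            "pendknee_parameter_error")
  if (zeta < 0) pk_stop("zeta must be >= 0", "pendknee_parameter_error")
  if (duration_s * fps < 10) {
    pk_stop("duration_s * fps must give at least 10 samples",
            "pendknee_parameter_error")
  }
  structure(list(omega_n = omega_n, zeta = zeta, theta_rest = theta_rest,
                 theta_release = theta_release, duration_s = duration_s,
                 fps = fps),
            class = "pendulum_model")
}

model_response <- function(model, t) {
  w <- model$omega_n
  z <- model$zeta
  A <- model$theta_release - model$theta_rest
  if (z < 1) {
    wd <- w * sqrt(1 - z^2)
    h <- exp(-z * w * t) * (cos(wd * t) +
                              z / sqrt(1 - z^2) * sin(wd * t))
  } else if (z == 1) {
    h <- exp(-w * t) * (1 + w * t)
  } else {
    s <- sqrt(z^2 - 1)
    h <- exp(-z * w * t) * (cosh(w * s * t) + z / s * sinh(w * s * t))
  }
  model$theta_rest + A * h
}

#' Simulate a pendulum-test angle trace
#'
#' Samples the model's closed-form response at `fps` and adds seeded
#' Gaussian measurement noise. Deterministic for a fixed seed; the global
#' RNG state is left untouched.
#'
#' @param model A [pendulum_model()].
#' @param noise_sd_deg Additive Gaussian noise SD in degrees.
#' @param seed Integer seed (NULL = use current RNG stream).
#' @return An [angle_trace()], device `"synthetic"`.
#' @export
simulate_trace <- function(model, noise_sd_deg = 0, seed = NULL) {
  stopifnot(inherits(model, "pendulum_model"))
  n <- round(model$duration_s * model$fps)
  t <- (seq_len(n) - 1) / model$fps
  theta <- model_response(model, t)
  if (noise_sd_deg > 0) {
    theta <- theta + with_local_seed(seed, stats::rnorm(n, 0, noise_sd_deg))
  }
  angle_trace(pmin(pmax(theta, 0), 180), fps = model$fps,
              device = "synthetic", smoothed = FALSE)
}

#' Closed-form swing landmarks of an underdamped model
#'
#' Analytic oracle for the landmark extraction: exact A0, A1, A3, A4 (and
#' extremum times `t_k = k pi / wd`) of the noise-free damped oscillator.
#' Only defined for 0 <= zeta < 1; at zeta >= 1 no oscillation exists.
#'
#' @param model A [pendulum_model()] with `zeta < 1`.
#' @return A `swing_landmarks` object with attribute `analytic = TRUE` and
#'   field `half_cycle_ratio` (r).
#' @export
closed_form_extrema <- function(model) {
  stopifnot(inherits(model, "pendulum_model"))
  z <- model$zeta
  if (z >= 1) {
    pk_stop("closed-form extrema require zeta < 1 (oscillatory regime)",
            "pendknee_parameter_error")
  }
  r <- exp(-pi * z / sqrt(1 - z^2))
  A <- abs(model$theta_release - model$theta_rest)
  wd <- model$omega_n * sqrt(1 - z^2)
  structure(list(A0 = A, A1 = A * (1 + r), A3 = A * r^2,
                 A4 = A * r^2 * (1 + r),
                 rest_angle = model$theta_rest, settled = TRUE,
                 half_cycle_ratio = r,
                 extremum_times = (1:3) * pi / wd),
            class = "swing_landmarks", analytic = TRUE)
}

#' Supine body geometry for the keypoint renderer
#'
#' Fixed skeleton of a subject supine on a bed, world units metres:
#' x from head toward feet, y vertical (up), z to the subject's left. The
#' test limb's thigh lies horizontal; the shank rotates about the knee in
#' the x-y (sagittal) plane by the trace's flexion angle. The
#' contralateral limb hangs at a fixed flexion angle.
#'
#' @param side Test limb, `"right"` (default) or `"left"`.
#' @param thigh_length,shank_length Segment lengths in metres.
#' @param hip_height Bed height of the hip axis, metres.
#' @param other_knee_deg Fixed flexion of the non-test limb, degrees.
#' @return Object of class `body_geometry`.
#' @export
body_geometry <- function(side = c("right", "left"), thigh_length = 0.45,
                          shank_length = 0.43, hip_height = 0.9,
                          other_knee_deg = 60) {
  side <- match.arg(side)
  if (thigh_length <= 0 || shank_length <= 0) {
    pk_stop("segment lengths must be positive", "pendknee_parameter_error")
  }
  structure(list(side = side, thigh_length = thigh_length,
                 shank_length = shank_length, hip_height = hip_height,
                 other_knee_deg = other_knee_deg),
            class = "body_geometry")
}

# static world-frame keypoints (metres); z > 0 is the subject's left
skeleton_static <- function(geom) {
  h <- geom$hip_height
  kp <- matrix(NA_real_, 17, 3,
               dimnames = list(.coco, c("x", "y", "z")))
  kp["nose", ]           <- c(-0.68, h + 0.12, 0)
  kp["left_eye", ]       <- c(-0.72, h + 0.14, 0.03)
  kp["right_eye", ]      <- c(-0.72, h + 0.14, -0.03)
  kp["left_ear", ]       <- c(-0.70, h + 0.10, 0.07)
  kp["right_ear", ]      <- c(-0.70, h + 0.10, -0.07)
  kp["left_shoulder", ]  <- c(-0.50, h, 0.18)
  kp["right_shoulder", ] <- c(-0.50, h, -0.18)
  kp["left_elbow", ]     <- c(-0.25, h + 0.02, 0.25)
  kp["right_elbow", ]    <- c(-0.25, h + 0.02, -0.25)
  kp["left_wrist", ]     <- c(0.00, h + 0.02, 0.27)
  kp["right_wrist", ]    <- c(0.00, h + 0.02, -0.27)
  kp["left_hip", ]       <- c(0, h, 0.12)
  kp["right_hip", ]      <- c(0, h, -0.12)
  kp
}

leg_points <- function(geom, hip, angle_deg) {
  th <- angle_deg * pi / 180
  knee <- hip + c(geom$thigh_length, 0, 0)
  ankle <- knee + geom$shank_length * c(cos(th), -sin(th), 0)
  list(knee = knee, ankle = ankle)
}

#' Render keypoint trajectories from an angle trace
#'
#' Embeds the angle trace in the supine skeleton and emits either 3D world
#' coordinates or a 2D orthographic camera projection with pixel noise and
#' near-0.9 confidences. The lateral (90 degree) view projects along the
#' mediolateral axis, so in-plane angles are preserved exactly at zero
#' noise; the 45 degree oblique view foreshortens the x-axis by cos(45).
#'
#' @param trace An [angle_trace()] driving the test limb's knee angle.
#' @param geom A [body_geometry()].
#' @param dims 2 (camera projection, pixels) or 3 (world coordinates).
#' @param view Camera azimuth for 2D rendering: `"90"` lateral (default)
#'   or `"45"` oblique.
#' @param noise_sd Coordinate noise SD: pixels for 2D, metres for 3D.
#' @param seed Integer seed for the noise and confidences.
#' @param px_per_m Pixels per metre of the orthographic camera.
#' @param image_center Pixel coordinates of the world origin.
#' @return A [keypoint_trajectory()].
#' @export
render_keypoints <- function(trace, geom = body_geometry(), dims = 2,
                             view = c("90", "45"), noise_sd = 0,
                             seed = NULL, px_per_m = 500,
                             image_center = c(960, 540)) {
  stopifnot(inherits(trace, "angle_trace"), inherits(geom, "body_geometry"))
  view <- match.arg(view)
  n <- length(trace$angles)
  world <- array(NA_real_, c(n, 17, 3))
  static <- skeleton_static(geom)
  hip_t <- static[paste0(geom$side, "_hip"), ]
  other <- if (geom$side == "right") "left" else "right"
  hip_o <- static[paste0(other, "_hip"), ]
  legs_o <- leg_points(geom, hip_o, geom$other_knee_deg)
  for (i in seq_len(n)) {
    kp <- static
    lt <- leg_points(geom, hip_t, trace$angles[i])
    kp[paste0(geom$side, "_knee"), ] <- lt$knee
    kp[paste0(geom$side, "_ankle"), ] <- lt$ankle
    kp[paste0(other, "_knee"), ] <- legs_o$knee
    kp[paste0(other, "_ankle"), ] <- legs_o$ankle
    world[i, , ] <- kp
  }

  if (dims == 3) {
    if (noise_sd > 0) {
      world <- world + with_local_seed(
        seed, array(stats::rnorm(length(world), 0, noise_sd), dim(world)))
    }
    return(keypoint_trajectory(world, fps = trace$fps,
                               source_tag = "3d-pose"))
  }

  # orthographic camera in the horizontal plane, azimuth measured from the
  # mediolateral axis; image y is down
  az <- if (view == "90") 0 else pi / 4
  e1 <- c(cos(az), 0, -sin(az))   # image x axis (horizontal)
  e2 <- c(0, 1, 0)                # world up -> image y (flipped below)
  px <- array(NA_real_, c(n, 17, 2))
  for (i in seq_len(n)) {
    P <- world[i, , ]
    px[i, , 1] <- (P %*% e1) * px_per_m + image_center[1]
    px[i, , 2] <- -(P %*% e2) * px_per_m + image_center[2]
  }
  res <- with_local_seed(seed, {
    noise <- if (noise_sd > 0)
      array(stats::rnorm(length(px), 0, noise_sd), dim(px))
    else array(0, dim(px))
    conf <- matrix(pmin(pmax(stats::rnorm(n * 17, 0.92, 0.02), 0), 1),
                   n, 17)
    list(noise = noise, conf = conf)
  })
  keypoint_trajectory(px + res$noise, fps = trace$fps,
                      confidence = res$conf, source_tag = "2d-pose")
}

#' Cohort specification for the synthetic study
#'
#' Defines the multi-subject layout: each subject has one affected limb
#' with a MAS level drawn from `mas_probs` and one unaffected limb at
#' MAS 0; every limb is tested `trials_per_limb` times and each trial is
#' recorded by three channels (goniometer trace, lateral 2D keypoints,
#' 3D keypoints) sharing the same underlying true swing. Spasticity maps
#' to damping through `zeta_mean`: higher MAS means a more damped swing
#' and therefore lower P1/P3. The mapping is a synthetic calibration that
#' spans the clinically observed ordering, not a clinical model.
#'
#' @param n_subjects Number of subjects (default 20).
#' @param trials_per_limb Trials per limb (default 5).
#' @param mas_levels Ordinal MAS levels available to affected limbs.
#' @param mas_probs Sampling probabilities over `mas_levels` (sum to 1).
#' @param zeta_mean Named map MAS level -> mean damping ratio.
#' @param zeta_sd Per-trial SD of the damping ratio.
#' @param zeta_range Truncation bounds for drawn damping ratios; the lower
#'   bound keeps every trace settled within `duration_s`.
#' @param gonio_noise_deg Goniometer channel noise SD, degrees.
#' @param pose2d_noise_px 2D keypoint noise SD, pixels.
#' @param pose3d_noise_m 3D keypoint noise SD, metres.
#' @param omega_n_mean,omega_n_sd Subject-level natural frequency, rad/s.
#' @param rest_mean,rest_sd Subject-level resting angle, degrees.
#' @param duration_s,fps Recording length and sampling rate.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 20, trials_per_limb = 5,
                        mas_levels = c(0, 1, 1.5, 2),
                        mas_probs = c(0.1, 0.3, 0.3, 0.3),
                        zeta_mean = c(`0` = 0.10, `1` = 0.25,
                                      `1.5` = 0.35, `2` = 0.45),
                        zeta_sd = 0.05, zeta_range = c(0.05, 0.95),
                        gonio_noise_deg = 0.25, pose2d_noise_px = 1.5,
                        pose3d_noise_m = 0.004,
                        omega_n_mean = 5.5, omega_n_sd = 0.4,
                        rest_mean = 70, rest_sd = 5,
                        duration_s = 12, fps = 30) {
  if (abs(sum(mas_probs) - 1) > 1e-9) {
    pk_stop("mas_probs must sum to 1", "pendknee_parameter_error")
  }
  zm <- zeta_mean[as.character(mas_levels)]
  if (anyNA(zm)) {
    pk_stop("zeta_mean must name every MAS level",
            "pendknee_parameter_error")
  }
  if (any(diff(zm) <= 0)) {
    pk_stop("zeta_mean must increase with MAS (spasticity damps the swing)",
            "pendknee_parameter_error")
  }
  spec <- as.list(environment())
  spec$zm <- NULL
  structure(spec, class = "cohort_spec")
}

truncnorm1 <- function(mean, sd, lo, hi) {
  min(max(stats::rnorm(1, mean, sd), lo), hi)
}

#' Generate a synthetic pendulum-test cohort on disk
#'
#' Draws subject- and trial-level parameters under `spec`, writes one
#' goniometer CSV, one 2D keypoint JSON (lateral view) and one 3D keypoint
#' CSV per trial into `out_dir`, and returns (and writes) the trial
#' metadata table and the ground-truth table (drawn damping ratio and
#' analytic P1/P3 per trial). Byte-identical output for a fixed seed.
#'
#' @param spec A [cohort_spec()].
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed.
#' @return List with `trial_table` (one row per trial x device, with file
#'   paths), `ground_truth`, and the paths of the two tables.
#' @export
simulate_cohort <- function(spec = cohort_spec(), out_dir, seed = 1) {
  stopifnot(inherits(spec, "cohort_spec"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  with_local_seed(seed, {
    meta <- list()
    truth <- list()
    for (s in seq_len(spec$n_subjects)) {
      sid <- sprintf("S%02d", s)
      affected_side <- sample(c("left", "right"), 1)
      mas_aff <- sample(spec$mas_levels, 1, prob = spec$mas_probs)
      omega_s <- truncnorm1(spec$omega_n_mean, spec$omega_n_sd, 3, 9)
      rest_s <- truncnorm1(spec$rest_mean, spec$rest_sd, 50, 90)
      for (limb in c("left", "right")) {
        affected <- limb == affected_side
        mas <- if (affected) mas_aff else 0
        zmu <- spec$zeta_mean[as.character(mas)]
        for (tr in seq_len(spec$trials_per_limb)) {
          zeta <- truncnorm1(zmu, spec$zeta_sd,
                             spec$zeta_range[1], spec$zeta_range[2])
          release <- truncnorm1(2, 1, 0, 8)
          model <- pendulum_model(omega_n = omega_s, zeta = zeta,
                                  theta_rest = rest_s,
                                  theta_release = release,
                                  duration_s = spec$duration_s,
                                  fps = spec$fps)
          true_trace <- simulate_trace(model, noise_sd_deg = 0)
          true_trace$side <- limb
          stem <- sprintf("%s_%s_t%d", sid, limb, tr)

          gonio <- true_trace
          gonio$angles <- pmin(pmax(
            gonio$angles + stats::rnorm(length(gonio$angles), 0,
                                        spec$gonio_noise_deg), 0), 180)
          p_gonio <- file.path(out_dir, paste0(stem, "_gonio.csv"))
          write_angle_csv(gonio, p_gonio)

          geom <- body_geometry(side = limb)
          k2 <- render_keypoints(true_trace, geom, dims = 2, view = "90",
                                 noise_sd = spec$pose2d_noise_px)
          p_2d <- file.path(out_dir, paste0(stem, "_pose2d.json"))
          write_keypoints_2d(k2, p_2d)

          k3 <- render_keypoints(true_trace, geom, dims = 3,
                                 noise_sd = spec$pose3d_noise_m)
          p_3d <- file.path(out_dir, paste0(stem, "_pose3d.csv"))
          write_keypoints_3d(k3, p_3d)

          base <- data.frame(subject_id = sid, limb = limb,
                             affected = affected,
                             mas_flexor = mas, mas_extensor = mas,
                             trial_index = tr,
                             stringsAsFactors = FALSE)
          meta[[length(meta) + 1]] <- rbind(
            cbind(base, device = "goniometer", camera_view = "none",
                  path = p_gonio),
            cbind(base, device = "pose2d", camera_view = "90",
                  path = p_2d),
            cbind(base, device = "pose3d", camera_view = "90",
                  path = p_3d))
          r <- exp(-pi * zeta / sqrt(1 - zeta^2))
          truth[[length(truth) + 1]] <- data.frame(
            subject_id = sid, limb = limb, trial_index = tr,
            zeta = zeta, analytic_P1 = 1 + r, analytic_P3 = 1 + r,
            stringsAsFactors = FALSE)
        }
      }
    }
    trial_table <- do.call(rbind, meta)
    ground_truth <- do.call(rbind, truth)
    tt_path <- file.path(out_dir, "trial_table.csv")
    gt_path <- file.path(out_dir, "ground_truth.csv")
    utils::write.csv(trial_table, tt_path, row.names = FALSE)
    utils::write.csv(ground_truth, gt_path, row.names = FALSE)
    list(trial_table = trial_table, ground_truth = ground_truth,
         trial_table_path = tt_path, ground_truth_path = gt_path)
  })
}
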