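# Readers/writers for the keypoint and angle-trace dialects.

make_2d_json <- function(path, n_frames = 3, kp_len = 51) {
  recs <- lapply(seq_len(n_frames), function(i) {
    kp <- as.numeric(rbind(1:17, (1:17) + i, 0.9))  # x, y, conf triplets
    list(image_id = sprintf("%06d.jpg", i - 1),
         keypoints = kp[seq_len(kp_len)],
         score = 0.9, idx = 0L)
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = I(17))
  path
}

test_that("2D reader parses a well-formed file and sorts frames", {
  f <- withr::local_tempfile(fileext = ".json")
  make_2d_json(f, n_frames = 3)
  traj <- read_keypoints_2d(f)
  expect_s3_class(traj, "keypoint_trajectory")
  expect_equal(traj$n_frames, 3)
  expect_equal(traj$dims, 2)
  expect_true(all(traj$confidence >= 0 & traj$confidence <= 1))
})

test_that("2D reader rejects malformed input with typed errors", {
  f <- withr::local_tempfile(fileext = ".json")
  writeLines("{not json", f)
  expect_error(read_keypoints_2d(f), class = "pendknee_parse_error")

  make_2d_json(f, kp_len = 50)
  expect_error(read_keypoints_2d(f), class = "pendknee_dialect_error")
  expect_error(read_keypoints_2d(f), "length 50")

  # two person records in one frame
  recs <- list(
    list(image_id = "0.jpg", keypoints = rep(0.5, 51), score = 1, idx = 0),
    list(image_id = "0.jpg", keypoints = rep(0.4, 51), score = 1, idx = 1))
  jsonlite::write_json(recs, f, auto_unbox = TRUE)
  expect_error(read_keypoints_2d(f), "single-subject",
               class = "pendknee_dialect_error")
})

test_that("renderer output round-trips bit-for-bit through both dialects", {
  m <- pendulum_model(zeta = 0.3, duration_s = 1, fps = 30)
  tr <- simulate_trace(m, noise_sd_deg = 0.5, seed = 11)
  g <- body_geometry("left")
  k2 <- render_keypoints(tr, g, dims = 2, noise_sd = 2, seed = 3)
  f2 <- withr::local_tempfile(fileext = ".json")
  write_keypoints_2d(k2, f2)
  back2 <- read_keypoints_2d(f2)
  expect_identical(as.numeric(back2$coords), as.numeric(k2$coords))
  expect_identical(as.numeric(back2$confidence),
                   as.numeric(k2$confidence))
  expect_equal(back2$n_frames, k2$n_frames)

  k3 <- render_keypoints(tr, g, dims = 3, noise_sd = 0.01, seed = 4)
  f3 <- withr::local_tempfile(fileext = ".csv")
  write_keypoints_3d(k3, f3)
  back3 <- read_keypoints_3d(f3)
  expect_identical(as.numeric(back3$coords), as.numeric(k3$coords))
})

test_that("3D reader validates frame completeness and finiteness", {
  f <- withr::local_tempfile(fileext = ".csv")
  df <- expand.grid(kp = 1:17, frame = 1:2)
  df$x <- rnorm(34); df$y <- rnorm(34); df$z <- rnorm(34)
  write.csv(df[, c("frame", "kp", "x", "y", "z")], f, row.names = FALSE)
  traj <- read_keypoints_3d(f)
  expect_equal(traj$n_frames, 2)
  expect_equal(traj$dims, 3)

  write.csv(df[!(df$frame == 2 & df$kp == 16), ], f, row.names = FALSE)
  err <- expect_error(read_keypoints_3d(f),
                      class = "pendknee_dialect_error")
  expect_match(conditionMessage(err), "frame 2")
  expect_match(conditionMessage(err), "16")

  df2 <- df; df2$z[5] <- NA
  write.csv(df2, f, row.names = FALSE)
  expect_error(read_keypoints_3d(f), class = "pendknee_dialect_error")
})

test_that("angle CSV reader infers fps and handles jitter and errors", {
  f <- withr::local_tempfile(fileext = ".csv")
  t <- (0:299) / 30
  write.csv(data.frame(time_s = t, angle_deg = 70 + sin(t)), f,
            row.names = FALSE)
  tr <- read_angle_csv(f)
  expect_equal(tr$fps, 30, tolerance = 1e-9)
  expect_equal(length(tr$angles), 300)

  # sawtooth jitter beyond 1%: resampled onto a uniform grid; values at
  # the original timestamps match an independent linear interpolation
  tj <- t + rep(c(0.0007, -0.0007), 150)
  ang <- 70 + 10 * sin(2 * pi * tj)
  write.csv(data.frame(time_s = tj, angle_deg = ang), f,
            row.names = FALSE)
  expect_message(trj <- read_angle_csv(f), "resampling")
  grid <- (seq_along(trj$angles) - 1) / trj$fps + tj[1]
  oracle <- approx(tj, ang, xout = grid, rule = 2)$y
  expect_equal(trj$angles, oracle, tolerance = 1e-9)

  # repeated timestamp
  tbad <- t; tbad[5] <- tbad[4]
  write.csv(data.frame(time_s = tbad, angle_deg = 70), f,
            row.names = FALSE)
  expect_error(read_angle_csv(f), class = "pendknee_parse_error")

  # too short
  write.csv(data.frame(time_s = t[1:5], angle_deg = 70), f,
            row.names = FALSE)
  expect_error(read_angle_csv(f), class = "pendknee_parameter_error")
})

test_that("clinical 180-at-extension convention converts on read", {
  f <- withr::local_tempfile(fileext = ".csv")
  t <- (0:29) / 30
  write.csv(data.frame(time_s = t, angle_deg = 180 - (0:29)), f,
            row.names = FALSE)
  tr <- read_angle_csv(f, convention = "extension_180")
  expect_equal(tr$angles, as.numeric(0:29))
})

test_that("trial table parses, maps MAS 1+ to 1.5 and rejects duplicates", {
  f <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(subject_id = "S01", limb = c("left", "right"),
                   affected = c(TRUE, FALSE),
                   mas_flexor = c("1+", "0"), mas_extensor = c("2", "0"),
                   device = "goniometer", camera_view = "none",
                   trial_index = 1)
  write.csv(df, f, row.names = FALSE)
  tt <- read_trial_table(f)
  expect_equal(tt$mas_flexor, c(1.5, 0))
  expect_equal(tt$mas_extensor, c(2, 0))

  write.csv(rbind(df, df[1, ]), f, row.names = FALSE)
  expect_error(read_trial_table(f), "duplicate",
               class = "pendknee_parse_error")

  df$mas_flexor <- c("2-", "0")
  write.csv(df, f, row.names = FALSE)
  expect_error(read_trial_table(f), "unknown MAS token",
               class = "pendknee_parse_error")
})

test_that("simulated cohort trial table has the full factorial layout", {
  dir <- withr::local_tempdir()
  out <- simulate_cohort(cohort_spec(n_subjects = 2, trials_per_limb = 2),
                         dir, seed = 5)
  tt <- read_trial_table(out$trial_table_path)
  # subjects x limbs x trials x devices
  expect_equal(nrow(tt), 2 * 2 * 2 * 3)
  expect_true(all(file.exists(file.path(tt$path))))
})
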