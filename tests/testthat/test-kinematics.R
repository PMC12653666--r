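# Knee-angle geometry and smoothing.

test_that("2D knee angle reproduces hand-computed poses", {
  # collinear thigh and shank: full extension
  tr <- knee_angle_2d(static_traj_2d(c(0, 0), c(0, 1), c(0, 2)))
  expect_angle_equal(tr, 0, 1e-9)
  # perpendicular segments
  tr <- knee_angle_2d(static_traj_2d(c(0, 0), c(0, 1), c(1, 1)))
  expect_angle_equal(tr, 90, 1e-9)
  # 45 degrees, cross-checked with the atan2 heading oracle
  tr <- knee_angle_2d(static_traj_2d(c(0, 0), c(1, 1), c(2, 1)))
  h1 <- atan2(1 - 0, 1 - 0)
  h2 <- atan2(1 - 1, 2 - 1)
  expect_angle_equal(tr, abs(h1 - h2) * 180 / pi, 1e-9)
  expect_angle_equal(tr, 45, 1e-9)
})

test_that("coincident keypoints raise a degenerate-geometry error", {
  expect_error(knee_angle_2d(static_traj_2d(c(0, 0), c(0, 0), c(1, 1))),
               "frame 1", class = "pendknee_degenerate_error")
})

test_that("2D angles are invariant to translation and uniform scaling", {
  m <- pendulum_model(zeta = 0.25, duration_s = 2)
  k <- render_keypoints(simulate_trace(m), body_geometry(), dims = 2,
                        noise_sd = 1, seed = 2)
  ref <- knee_angle_2d(k, "right")
  for (tf in list(c(123.4, -56.7), c(-1000, 0.5))) {
    k2 <- k
    k2$coords[, , 1] <- k2$coords[, , 1] + tf[1]
    k2$coords[, , 2] <- k2$coords[, , 2] + tf[2]
    expect_equal(knee_angle_2d(k2, "right")$angles, ref$angles,
                 tolerance = 1e-9)
  }
  for (s in c(0.01, 3.7)) {
    k2 <- k
    k2$coords <- k2$coords * s
    expect_equal(knee_angle_2d(k2, "right")$angles, ref$angles,
                 tolerance = 1e-9)
  }
})

test_that("low-confidence frames are interpolated, not dropped", {
  m <- pendulum_model(zeta = 0.25, duration_s = 2)
  k <- render_keypoints(simulate_trace(m), body_geometry(), dims = 2,
                        seed = 2)
  ref <- knee_angle_2d(k, "right")
  k$confidence[10, coco_index_for_test("right_knee")] <- 0.1
  tr <- knee_angle_2d(k, "right")
  expect_equal(length(tr$angles), k$n_frames)
  expect_equal(attr(tr, "n_interpolated"), 1L)
  # filled value is the linear interpolation of its neighbours
  expect_equal(tr$angles[10], (ref$angles[9] + ref$angles[11]) / 2,
               tolerance = 1e-9)
})

test_that("sagittal-plane normal matches the hand cross product", {
  # upright skeleton: longitudinal down, second midline vector
  # mediolateral; the normal is the walking (anteroposterior) axis
  n <- plane_normal(c(0, -1, 0), c(1, 0, 0))
  expect_equal(abs(sum(n * c(0, 0, 1))), 1, tolerance = 1e-12)
  expect_error(plane_normal(c(0, -1, 0), c(0, 2, 0)),
               class = "pendknee_degenerate_error")
})

test_that("out-of-plane projection reproduces the hand example", {
  n <- c(1, 0, 0)
  uh <- drop(pendknee:::project_out(matrix(c(1, 0, -1), 1), matrix(n, 1)))
  vh <- drop(pendknee:::project_out(matrix(c(0, 1, -1), 1), matrix(n, 1)))
  expect_equal(uh, c(0, 0, -1))
  expect_equal(vh, c(0, 1, -1))
  ang <- pendknee:::angle_rows(matrix(uh, 1), matrix(vh, 1))
  expect_equal(ang, 45, tolerance = 1e-12)
})

test_that("3D angles are invariant to rigid rotation and the plane normal
           co-rotates", {
  m <- pendulum_model(zeta = 0.25, duration_s = 2)
  k <- render_keypoints(simulate_trace(m), body_geometry(), dims = 3,
                        noise_sd = 0.005, seed = 9)
  ref <- knee_angle_3d(k, "right")
  refn <- sagittal_plane(k)$n
  set.seed(31)
  for (rep in 1:3) {
    R <- random_rotation()
    k2 <- k
    for (i in seq_len(k$n_frames)) {
      k2$coords[i, , ] <- k$coords[i, , ] %*% t(R)
    }
    expect_equal(knee_angle_3d(k2, "right")$angles, ref$angles,
                 tolerance = 1e-6)
    n2 <- sagittal_plane(k2)$n
    expect_equal(abs(rowSums(n2 * (refn %*% t(R)))),
                 rep(1, nrow(n2)), tolerance = 1e-9)
  }
})

test_that("3D equals 2D for the simulator's planar lateral motion", {
  m <- pendulum_model(zeta = 0.2, duration_s = 3)
  tr <- simulate_trace(m)
  g <- body_geometry("right")
  a2 <- knee_angle_2d(render_keypoints(tr, g, dims = 2, view = "90"),
                      "right")
  a3 <- knee_angle_3d(render_keypoints(tr, g, dims = 3), "right")
  expect_equal(a2$angles, a3$angles, tolerance = 1e-6)
  expect_equal(a3$angles, tr$angles, tolerance = 1e-6)
})

test_that("segment parallel to the plane normal is a degenerate projection", {
  m <- pendulum_model(zeta = 0.2, duration_s = 1)
  k <- render_keypoints(simulate_trace(m), body_geometry("right"),
                        dims = 3)
  # push the right ankle mediolaterally so the shank || normal (z axis)
  knee <- k$coords[, coco_index_for_test("right_knee"), ]
  k$coords[, coco_index_for_test("right_ankle"), ] <-
    knee + matrix(rep(c(0, 0, -0.43), each = k$n_frames), ncol = 3)
  expect_error(knee_angle_3d(k, "right"),
               class = "pendknee_degenerate_error")
})

test_that("smoother reproduces cubics exactly and passes constants through", {
  t <- 0:199
  cubic <- 40 + 0.3 * t - 2e-3 * t^2 + 4e-6 * t^3
  tr <- angle_trace(cubic, fps = 30)
  sm <- smooth_trace(tr)
  expect_true(sm$smoothed)
  expect_equal(sm$angles, cubic, tolerance = 1e-9)
  const <- angle_trace(rep(70, 50), fps = 30)
  expect_equal(smooth_trace(const)$angles, rep(70, 50))
})

test_that("smoothing strictly reduces RMS noise on noisy cubics", {
  t <- 0:199
  cubic <- 40 + 0.3 * t - 2e-3 * t^2 + 4e-6 * t^3
  set.seed(104)
  wins <- 0
  for (rep in 1:100) {
    noisy <- cubic + rnorm(length(t), 0, 1)
    sm <- smooth_trace(angle_trace(noisy, fps = 30))
    rms_before <- sqrt(mean((noisy - cubic)^2))
    rms_after <- sqrt(mean((sm$angles - cubic)^2))
    wins <- wins + (rms_after < rms_before)
  }
  expect_equal(wins, 100)
})

test_that("smoother parameter validation", {
  tr <- angle_trace(rep(70, 50), fps = 30)
  expect_error(smooth_trace(tr, window_frames = 10),
               class = "pendknee_parameter_error")
  expect_error(smooth_trace(tr, window_frames = 3),
               class = "pendknee_parameter_error")
  expect_error(smooth_trace(tr, window_frames = 51),
               class = "pendknee_parameter_error")
  expect_error(smooth_trace(tr, window_frames = 11, polyorder = 11),
               class = "pendknee_parameter_error")
})
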