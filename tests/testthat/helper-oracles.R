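# Independent oracles kept deliberately naive: explicit loops and first
# differences, no reuse of package internals.

# brute-force turning-point scan (strict neighbours; signals without
# plateaus only)
brute_extrema <- function(x) {
  idx <- integer(0)
  kind <- character(0)
  for (i in 2:(length(x) - 1)) {
    if (x[i] > x[i - 1] && x[i] > x[i + 1]) {
      idx <- c(idx, i); kind <- c(kind, "peak")
    } else if (x[i] < x[i - 1] && x[i] < x[i + 1]) {
      idx <- c(idx, i); kind <- c(kind, "trough")
    }
  }
  data.frame(frame_index = idx, angle = x[idx], kind = kind)
}

# two-way ANOVA ICC (consistency) by explicit sums of squared deviations
brute_icc_consistency <- function(m) {
  n <- nrow(m); k <- ncol(m)
  gm <- mean(m)
  ssr <- 0
  for (i in seq_len(n)) ssr <- ssr + k * (mean(m[i, ]) - gm)^2
  ssc <- 0
  for (j in seq_len(k)) ssc <- ssc + n * (mean(m[, j]) - gm)^2
  sst <- 0
  for (i in seq_len(n)) for (j in seq_len(k)) sst <- sst + (m[i, j] - gm)^2
  msr <- ssr / (n - 1)
  mse <- (sst - ssr - ssc) / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse)
}

coco_index_for_test <- function(name) match(name, coco_keypoints())

# random rigid rotation (QR with positive-determinant fix)
random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# a 2D trajectory holding one fixed pose (legs configurable), >= 10 frames
# so downstream angle traces satisfy their length invariant
static_traj_2d <- function(hip, knee, ankle, side = "right",
                           n_frames = 12) {
  co <- array(0, c(n_frames, 17, 2))
  for (i in seq_len(n_frames)) {
    base <- matrix(rep(c(5, 5), 17), ncol = 2, byrow = TRUE)
    base[pendknee:::coco_index(paste0(side, "_hip")), ] <- hip
    base[pendknee:::coco_index(paste0(side, "_knee")), ] <- knee
    base[pendknee:::coco_index(paste0(side, "_ankle")), ] <- ankle
    # spread the remaining keypoints so no pair coincides
    others <- setdiff(1:17, pendknee:::leg_indices(side))
    base[others, 1] <- base[others, 1] + seq_along(others)
    co[i, , ] <- base
  }
  keypoint_trajectory(co, fps = 30, source_tag = "2d-pose")
}

expect_angle_equal <- function(trace, value, tol) {
  expect_true(all(abs(trace$angles - value) < tol))
}
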