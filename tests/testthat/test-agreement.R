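# Agreement statistics against hand computations and naive oracles.

test_that("Bland-Altman bias, limits and proportional-bias regression", {
  x <- c(1, 2, 3, 4)
  y <- x
  ba <- bland_altman(x, y)
  expect_equal(ba$bias, 0)
  expect_equal(ba$loa_low, 0)
  expect_equal(ba$loa_high, 0)
  expect_true(ba$degenerate)

  ba <- bland_altman(c(1, 2, 3), c(2, 3, 4))
  expect_equal(ba$bias, 1)
  expect_equal(ba$loa_high - ba$loa_low, 0)

  # hand OLS: y = 1.2 x - 0.1, so d = 0.2 x - 0.1 and m = 1.1 x - 0.05;
  # the slope of d on m is 0.2 / 1.1
  ba <- bland_altman(c(1, 2, 3, 4), c(1.1, 2.3, 3.5, 4.7))
  expect_equal(ba$bias, 0.4)
  expect_equal(ba$prop_bias_slope, 2 / 11, tolerance = 1e-12)
  expect_equal(ba$bias + mean(c(1, 2, 3, 4)),
               mean(c(1.1, 2.3, 3.5, 4.7)))
})

test_that("consistency ICC reproduces the worked 3x2 matrix", {
  m <- rbind(c(1, 2), c(2, 4), c(3, 6))
  r <- icc_consistency(m)
  expect_equal(unname(r$ms["MSR"]), 4.5)
  expect_equal(unname(r$ms["MSE"]), 0.5)
  expect_equal(r$icc, 0.8, tolerance = 1e-12)
  expect_lte(r$ci_low, r$icc)
  expect_gte(r$ci_high, r$icc)
})

test_that("consistency ICC ignores a constant between-method offset", {
  set.seed(5)
  a <- rnorm(20, 10, 3)
  r <- icc_consistency(cbind(a, a + 5))
  expect_equal(r$icc, 1, tolerance = 1e-9)
})

test_that("ICC agrees with the brute-force ANOVA oracle", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(5:10, 1)
    k <- sample(2:3, 1)
    m <- matrix(rnorm(n * k, 50, 10), n, k) +
      rnorm(n, 0, sample(c(0.5, 5), 1))
    expect_equal(icc_consistency(m)$icc, brute_icc_consistency(m),
                 tolerance = 1e-10)
  }
})

test_that("ICC on independent noise is near zero and can go negative", {
  set.seed(99)
  r <- icc_consistency(cbind(rnorm(200), rnorm(200)))
  expect_lt(abs(r$icc), 0.15)
  expect_error(icc_consistency(rbind(c(1, NA), c(2, 2), c(3, 3))),
               class = "pendknee_parameter_error")
})

test_that("paired limb comparison: arithmetic, degenerate and power", {
  pc <- paired_limb_comparison(c(0.7, 0.8, 0.9), c(1.0, 1.1, 1.2))
  expect_equal(pc$mean_diff, -0.3, tolerance = 1e-12)
  expect_equal(pc$mean_a - pc$mean_b, pc$mean_diff)

  pc <- paired_limb_comparison(c(1, 2, 3), c(1, 2, 3))
  expect_true(pc$degenerate)
  expect_true(is.na(pc$p_value))

  set.seed(12)
  aff <- rnorm(20, 0.75, 0.05)
  unaff <- aff + 0.35 + rnorm(20, 0, 0.1)
  pc <- paired_limb_comparison(aff, unaff)
  expect_lt(abs(pc$mean_diff + 0.35), 0.07)
  expect_lt(pc$p_value, 0.001)
  expect_lt(pc$d_paired, 0)
})

test_that("paired t-test holds its nominal type-I error", {
  set.seed(2024)
  rejections <- 0
  for (rep in 1:2000) {
    a <- rnorm(20)
    b <- rnorm(20)
    rejections <- rejections +
      (paired_limb_comparison(a, b)$p_value < 0.05)
  }
  rate <- 100 * rejections / 2000
  expect_gte(rate, 3.5)
  expect_lte(rate, 6.5)
})

test_that("IQR fence removes the planted outlier and spares constants", {
  f <- iqr_filter(c(1, 2, 3, 4, 100))
  expect_equal(f$kept, c(1, 2, 3, 4))
  expect_equal(f$removed_count, 1L)
  # quartiles by linear interpolation: Q1 = 2, Q3 = 4, upper fence 7
  expect_equal(f$fences, c(-1, 7))

  f <- iqr_filter(rep(5, 10))
  expect_equal(f$removed_count, 0L)
})

test_that("IQR removal fraction on normal data matches theory", {
  set.seed(8)
  f <- iqr_filter(rnorm(10000))
  frac <- 100 * f$removed_count / 10000
  expect_gt(frac, 0.4)
  expect_lt(frac, 1.0)
})

test_that("Spearman equals Pearson on midranks and is monotone-invariant", {
  params <- c(1.2, 1.1, 0.9, 0.8, 0.5, 0.4)
  mas <- c(0, 0, 1, 1, 2, 2)
  r <- spearman_mas(params, mas, screen = FALSE)
  expect_equal(r$rho, cor(rank(params), rank(mas)), tolerance = 1e-12)

  # strictly decreasing, no ties
  r <- spearman_mas(c(5, 4, 3, 2, 1), c(1, 2, 3, 4, 5), screen = FALSE)
  expect_equal(r$rho, -1)

  # invariance under strictly monotone transforms of the parameters
  r1 <- spearman_mas(params, mas, screen = FALSE)
  r2 <- spearman_mas(exp(3 * params), mas, screen = FALSE)
  expect_equal(r1$rho, r2$rho, tolerance = 1e-12)

  # all-tied MAS is degenerate, not an error
  r <- spearman_mas(params, rep(1, 6), screen = FALSE)
  expect_true(r$degenerate)
})

test_that("Spearman screening drops fence outliers before correlating", {
  params <- c(1.2, 1.1, 0.9, 0.8, 0.5, 0.4, 50)
  mas <- c(0, 0, 1, 1, 2, 2, 0)
  r <- spearman_mas(params, mas)
  expect_equal(r$n_removed, 1L)
  expect_equal(r$n_used, 6L)
})

test_that("Shapiro gate: nominal pass rate, power and degeneracy", {
  set.seed(61)
  passes <- 0
  for (rep in 1:200) {
    passes <- passes + shapiro_gate(rnorm(50))$pass
  }
  expect_gte(passes / 200, 0.92)
  expect_lte(passes / 200, 0.98)

  fails <- 0
  for (rep in 1:100) {
    fails <- fails + !shapiro_gate(rexp(200))$pass
  }
  expect_gte(fails / 100, 0.95)

  expect_error(shapiro_gate(c(1, 2)), class = "pendknee_parameter_error")
  expect_true(shapiro_gate(rep(3, 10))$degenerate)
})

test_that("study report builds all three tables and ignores row order", {
  dir <- withr::local_tempdir()
  out <- simulate_cohort(cohort_spec(n_subjects = 4, trials_per_limb = 3,
                                     mas_probs = c(0, 0.3, 0.3, 0.4)),
                         dir, seed = 21)
  trials <- analyze_cohort(out$trial_table)
  rep1 <- study_report(trials)
  expect_s3_class(rep1, "study_report")
  expect_true(all(c("device", "stratum", "parameter", "icc") %in%
                    names(rep1$icc)))
  expect_equal(sort(unique(rep1$icc$device)), c("pose2d", "pose3d"))
  expect_equal(nrow(rep1$limbs), 3 * 3)   # devices x parameters
  expect_equal(nrow(rep1$spearman), 3 * 2 * 3)

  set.seed(3)
  shuffled <- trials[sample(nrow(trials)), ]
  rep2 <- study_report(shuffled)
  expect_equal(rep2$icc$icc, rep1$icc$icc)
  expect_equal(rep2$limbs$effect, rep1$limbs$effect)
  expect_equal(rep2$spearman$rho, rep1$spearman$rho)
})

test_that("cells with failed preconditions are reported unavailable", {
  dir <- withr::local_tempdir()
  out <- simulate_cohort(cohort_spec(n_subjects = 1, trials_per_limb = 1),
                         dir, seed = 13)
  trials <- analyze_cohort(out$trial_table)
  rep <- study_report(trials)
  expect_true(all(grepl("unavailable", rep$icc$note)))
  expect_true(all(is.na(rep$icc$icc)))
  expect_true(all(grepl("unavailable", rep$limbs$note)))
})

test_that("table writers emit CSV and JSON for every table", {
  dir <- withr::local_tempdir()
  out <- simulate_cohort(cohort_spec(n_subjects = 3, trials_per_limb = 2),
                         dir, seed = 33)
  rep <- study_report(analyze_cohort(out$trial_table))
  tdir <- file.path(dir, "tables")
  files <- write_study_tables(rep, tdir)
  expect_true(all(file.exists(files)))
  expect_true(file.exists(file.path(tdir, "table1_icc.csv")))
  expect_true(file.exists(file.path(tdir, "table2_limbs.json")))
  back <- read.csv(file.path(tdir, "table1_icc.csv"))
  expect_equal(nrow(back), nrow(rep$icc))
})
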