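# Method-agreement statistics: Bland-Altman with proportional-bias
# regression, two-way random-effects consistency ICC, paired limb
# comparison with effect size, IQR outlier screening, Spearman correlation
# against ordinal MAS scores, and a Shapiro-Wilk normality gate. Alpha is
# 0.05 throughout and no multiplicity correction is applied.

#' Bland-Altman agreement analysis
#'
#' Bias (mean of `y - x`), 95% limits of agreement (bias +/- 1.96 SD of the
#' differences), and a proportional-bias check: ordinary least-squares
#' regression of the difference on the pairwise mean, with the slope's
#' two-sided p-value. Zero-variance differences collapse the limits onto
#' the bias and leave the regression undefined (flagged).
#'
#' @param x Reference-method values (e.g. goniometer).
#' @param y Comparison-method values (e.g. pose-derived), same length,
#'   pairwise aligned; length >= 3.
#' @return Object of class `bland_altman`: `bias`, `loa_low`, `loa_high`,
#'   `prop_bias_slope`, `prop_bias_r2`, `prop_bias_p`, `degenerate`, plus
#'   the per-pair `mean` and `difference` vectors for plotting.
#' @export
bland_altman <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    pk_stop("bland_altman needs paired vectors of equal length >= 3",
            "pendknee_parameter_error")
  }
  d <- y - x
  m <- (x + y) / 2
  bias <- mean(d)
  sdd <- stats::sd(d)
  degenerate <- !is.finite(sdd) || sdd < 1e-12
  if (degenerate) {
    slope <- r2 <- p <- NA_real_
    loa <- c(bias, bias)
  } else {
    loa <- bias + c(-1.96, 1.96) * sdd
    if (stats::sd(m) < 1e-12) {
      slope <- r2 <- p <- NA_real_
    } else {
      fit <- stats::lm(d ~ m)
      # exactly linear difference patterns are legitimate input; silence
      # summary.lm's perfect-fit note
      sm <- suppressWarnings(summary(fit))
      slope <- unname(stats::coef(fit)[2])
      r2 <- sm$r.squared
      p <- sm$coefficients[2, 4]
    }
  }
  structure(list(bias = bias, loa_low = loa[1], loa_high = loa[2],
                 prop_bias_slope = slope, prop_bias_r2 = r2,
                 prop_bias_p = p, degenerate = degenerate,
                 mean = m, difference = d, n = length(x)),
            class = "bland_altman")
}

#' Two-way random-effects consistency ICC
#'
#' Single-rater intraclass correlation from the two-way random-effects
#' model in its consistency form,
#' `ICC = (MSR - MSE) / (MSR + (k - 1) MSE)`,
#' where MSR and MSE are the between-subject and residual mean squares of
#' the subjects x raters ANOVA decomposition. Rater (column) main effects
#' are excluded from the error term, so a constant offset between methods
#' does not lower the coefficient. The 95% confidence interval uses the
#' exact F-distribution bounds for this form. A coefficient below zero
#' (MSR < MSE) is reported as-is and flagged, not clamped.
#'
#' @param values Complete numeric matrix, subjects in rows, raters/methods
#'   in columns; >= 3 rows, >= 2 columns, no missing cells.
#' @param conf_level Confidence level, default 0.95.
#' @return Object of class `icc_result`: `icc`, `ci_low`, `ci_high`,
#'   `model_tag`, `n_subjects`, `n_raters`, `ms` (the mean squares),
#'   `negative` flag.
#' @export
icc_consistency <- function(values, conf_level = 0.95) {
  values <- as.matrix(values)
  n <- nrow(values)
  k <- ncol(values)
  if (n < 3 || k < 2) {
    pk_stop("ICC needs >= 3 subjects and >= 2 raters",
            "pendknee_parameter_error")
  }
  if (anyNA(values)) {
    pk_stop("ICC requires a complete-case matrix (no missing cells)",
            "pendknee_parameter_error")
  }
  gm <- mean(values)
  rm_ <- rowMeans(values)
  cm <- colMeans(values)
  ssr <- k * sum((rm_ - gm)^2)
  ssc <- n * sum((cm - gm)^2)
  sst <- sum((values - gm)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  mse <- sse / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse)

  alpha <- 1 - conf_level
  if (mse < 1e-300) {
    ci <- c(icc, icc)
  } else {
    fobs <- msr / mse
    df1 <- n - 1
    df2 <- (n - 1) * (k - 1)
    fl <- fobs / stats::qf(1 - alpha / 2, df1, df2)
    fu <- fobs * stats::qf(1 - alpha / 2, df2, df1)
    ci <- c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1))
  }
  structure(list(icc = icc, ci_low = ci[1], ci_high = ci[2],
                 model_tag = "two-way random, single rater, consistency",
                 n_subjects = n, n_raters = k,
                 ms = c(MSR = msr, MSC = ssc / (k - 1), MSE = mse),
                 negative = icc < 0),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(%s) = %.3f [%.3f, %.3f], n = %d x %d%s\n",
              "consistency", x$icc, x$ci_low, x$ci_high,
              x$n_subjects, x$n_raters,
              if (x$negative) " (negative, flagged)" else ""))
  invisible(x)
}

#' Paired comparison of affected vs unaffected limbs
#'
#' Group means and SDs, the raw mean difference
#' `mean(affected) - mean(unaffected)`, a two-sided paired t-test, and the
#' paired effect size `d = mean(differences) / sd(differences)`. Inputs
#' must be subject-aligned. All-zero differences are a degenerate case:
#' the test is undefined and flagged.
#'
#' @param affected,unaffected Subject-aligned numeric vectors, length >= 3.
#' @return Object of class `paired_comparison` with fields `mean_a`,
#'   `sd_a`, `mean_b`, `sd_b`, `mean_diff`, `t_stat`, `p_value`,
#'   `d_paired`, `n`, `degenerate`.
#' @export
paired_limb_comparison <- function(affected, unaffected) {
  if (length(affected) != length(unaffected) || length(affected) < 3) {
    pk_stop("paired comparison needs aligned vectors of equal length >= 3",
            "pendknee_parameter_error")
  }
  d <- affected - unaffected
  sdd <- stats::sd(d)
  if (!is.finite(sdd) || sdd < 1e-12) {
    return(structure(list(
      mean_a = mean(affected), sd_a = stats::sd(affected),
      mean_b = mean(unaffected), sd_b = stats::sd(unaffected),
      mean_diff = mean(d), t_stat = NA_real_, p_value = NA_real_,
      d_paired = NA_real_, n = length(d), degenerate = TRUE),
      class = "paired_comparison"))
  }
  tt <- stats::t.test(affected, unaffected, paired = TRUE)
  structure(list(
    mean_a = mean(affected), sd_a = stats::sd(affected),
    mean_b = mean(unaffected), sd_b = stats::sd(unaffected),
    mean_diff = mean(d),
    t_stat = unname(tt$statistic), p_value = tt$p.value,
    d_paired = mean(d) / sdd, n = length(d), degenerate = FALSE),
    class = "paired_comparison")
}

#' Tukey-fence outlier screening
#'
#' Removes values outside `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]`, with quartiles by
#' linear interpolation of order statistics (`quantile(type = 7)`). Used to
#' drop trials contaminated by inadequate muscle relaxation before the
#' MAS correlation analysis.
#'
#' @param values Numeric vector, length >= 4.
#' @param k Fence multiplier, default 1.5.
#' @return List with `kept`, `removed_count`, `kept_idx`, `fences`.
#' @export
iqr_filter <- function(values, k = 1.5) {
  if (length(values) < 4) {
    pk_stop("iqr_filter needs at least 4 values",
            "pendknee_parameter_error")
  }
  q <- stats::quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
  fences <- c(q[1] - k * (q[2] - q[1]), q[2] + k * (q[2] - q[1]))
  keep <- values >= fences[1] & values <= fences[2]
  list(kept = values[keep], removed_count = sum(!keep),
       kept_idx = which(keep), fences = fences)
}

#' Spearman correlation of pendulum parameters with MAS scores
#'
#' Rank correlation with midrank ties (MAS scores are heavily tied) and
#' asymptotic two-sided p-value, after Tukey-fence screening of the
#' parameter values ([iqr_filter()]). All-tied MAS input leaves the
#' coefficient undefined (flagged).
#'
#' @param params Numeric parameter values (one per trial), length >= 5
#'   after screening.
#' @param mas Aligned ordinal MAS levels (0, 1, 1.5, 2, 3, 4).
#' @param screen Apply IQR screening to `params` first (default TRUE).
#' @return Object of class `correlation_result`: `rho`, `p_value`,
#'   `n_used`, `n_removed`, `degenerate`.
#' @export
spearman_mas <- function(params, mas, screen = TRUE) {
  if (length(params) != length(mas) || length(params) < 5) {
    pk_stop("spearman_mas needs aligned vectors of equal length >= 5",
            "pendknee_parameter_error")
  }
  removed <- 0L
  if (screen) {
    f <- iqr_filter(params)
    removed <- f$removed_count
    mas <- mas[f$kept_idx]
    params <- f$kept
  }
  if (length(params) < 5) {
    pk_stop("fewer than 5 pairs remain after outlier screening",
            "pendknee_parameter_error")
  }
  if (length(unique(mas)) < 2) {
    return(structure(list(rho = NA_real_, p_value = NA_real_,
                          n_used = length(params), n_removed = removed,
                          degenerate = TRUE),
                     class = "correlation_result"))
  }
  ct <- suppressWarnings(
    stats::cor.test(params, mas, method = "spearman", exact = FALSE))
  structure(list(rho = unname(ct$estimate), p_value = ct$p.value,
                 n_used = length(params), n_removed = removed,
                 degenerate = FALSE),
            class = "correlation_result")
}

#' Shapiro-Wilk normality gate
#'
#' Tests the between-method differences for normality before the paired
#' t-test and Bland-Altman analyses. The gate annotates rather than
#' blocks: downstream analyses proceed either way and carry the flag.
#'
#' @param differences Numeric vector, 3 <= n <= 5000.
#' @param alpha Significance level for the pass flag, default 0.05.
#' @return List with `statistic`, `p_value`, `pass` (p > alpha),
#'   `degenerate` (constant input).
#' @export
shapiro_gate <- function(differences, alpha = 0.05) {
  n <- length(differences)
  if (n < 3 || n > 5000) {
    pk_stop("shapiro_gate requires 3 <= n <= 5000",
            "pendknee_parameter_error")
  }
  if (stats::sd(differences) < 1e-12) {
    return(list(statistic = NA_real_, p_value = NA_real_, pass = NA,
                degenerate = TRUE))
  }
  sw <- stats::shapiro.test(differences)
  list(statistic = unname(sw$statistic), p_value = sw$p.value,
       pass = sw$p.value > alpha, degenerate = FALSE)
}
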