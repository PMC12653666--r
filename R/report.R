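# Study-level driver: per-trial parameter extraction and the three result
# tables of a method-agreement study -- cross-device ICC grid, paired
# affected-vs-unaffected limb comparison, and Spearman correlation of the
# pendulum parameters with MAS scores.

#' Analyze a single trial file into pendulum parameters
#'
#' Reads the per-trial input for its device (goniometer CSV, 2D keypoint
#' JSON, or 3D keypoint file), derives the knee-angle trace, smooths it,
#' and extracts landmarks and parameters. Overdamped traces yield a row
#' with whatever landmarks were measurable and `quality = "overdamped"`.
#'
#' @param path Input file path.
#' @param device `"goniometer"`, `"pose2d"` or `"pose3d"`.
#' @param side `"left"` or `"right"` (ignored for goniometer input).
#' @param config A [run_config()].
#' @param fps Frames per second for keypoint inputs.
#' @return One-row `data.frame`: A0, A1, A3, A4, rest_angle, P1, P2, P3,
#'   quality.
#' @export
analyze_trial <- function(path, device, side = "right",
                          config = run_config(), fps = 30) {
  trace <- switch(device,
    goniometer = read_angle_csv(path, convention = config$angle.convention),
    pose2d = knee_angle_2d(read_keypoints_2d(path, fps = fps), side,
                           config),
    pose3d = knee_angle_3d(read_keypoints_3d(path, fps = fps), side,
                           config),
    pk_stop(sprintf("unknown device '%s'", device),
            "pendknee_parameter_error"))
  sm <- smooth_trace(trace, config = config)
  lm_or_partial <- tryCatch(
    list(lm = swing_landmarks(sm, config = config), quality = "ok"),
    pendknee_overdamped_error = function(e) {
      list(lm = pk_condition_data(e)$partial, quality = "overdamped")
    })
  lmk <- lm_or_partial$lm
  params <- tryCatch(pendulum_parameters(lmk),
                     pendknee_parameter_error = function(e) {
                       list(P1 = NA_real_, P2 = NA_real_, P3 = NA_real_)
                     })
  quality <- lm_or_partial$quality
  if (quality == "ok" && !isTRUE(lmk$settled)) quality <- "unsettled"
  data.frame(A0 = lmk$A0, A1 = lmk$A1, A3 = lmk$A3, A4 = lmk$A4,
             rest_angle = lmk$rest_angle,
             P1 = params$P1, P2 = params$P2, P3 = params$P3,
             quality = quality, stringsAsFactors = FALSE)
}

#' Analyze every trial of a cohort
#'
#' Joins the trial-metadata table with per-trial pendulum parameters.
#'
#' @param trial_table Data frame as returned by [read_trial_table()] or
#'   [simulate_cohort()]; must carry a `path` column.
#' @param config A [run_config()].
#' @return The metadata table with A0..A4, P1..P3 and `quality` columns
#'   appended (one row per trial x device).
#' @export
analyze_cohort <- function(trial_table, config = run_config()) {
  if (is.null(trial_table$path)) {
    pk_stop("trial table must carry a 'path' column",
            "pendknee_parameter_error")
  }
  missing <- !file.exists(trial_table$path)
  if (any(missing)) {
    pk_stop(sprintf("trial input file not found (row %d): %s",
                    which(missing)[1], trial_table$path[which(missing)[1]]),
            "pendknee_parse_error")
  }
  res <- lapply(seq_len(nrow(trial_table)), function(i) {
    analyze_trial(trial_table$path[i], trial_table$device[i],
                  trial_table$limb[i], config)
  })
  cbind(trial_table, do.call(rbind, res))
}

param_cols <- c("P1", "P2", "P3")

# pair each pose device's trials with the goniometer rows on
# (subject, limb, trial); returns a merged frame with <param>.gonio
pair_with_gonio <- function(trials, device) {
  key <- c("subject_id", "limb", "trial_index")
  g <- trials[trials$device == "goniometer",
              c(key, "affected", param_cols)]
  d <- trials[trials$device == device,
              c(key, "camera_view", param_cols)]
  merge(g, d, by = key, suffixes = c(".gonio", ""))
}

icc_cell <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3) {
    return(data.frame(icc = NA_real_, ci_low = NA_real_,
                      ci_high = NA_real_, n = sum(ok),
                      note = "unavailable (n < 3)"))
  }
  r <- icc_consistency(cbind(x[ok], y[ok]))
  data.frame(icc = r$icc, ci_low = r$ci_low, ci_high = r$ci_high,
             n = r$n_subjects, note = "")
}

#' Study-level result tables
#'
#' Builds the three tables of a device-agreement study from per-trial
#' records ([analyze_cohort()] output):
#'
#' * `icc`: consistency ICC of each pose device against the goniometer,
#'   per parameter, stratified by affected/unaffected limb (with camera
#'   view when a device was recorded from several) plus overall.
#' * `limbs`: paired affected-vs-unaffected comparison per device and
#'   parameter, on subject-level trial means; the `effect` column is the
#'   raw mean difference (the convention of the clinical literature's
#'   summary tables), with the standardized `d_paired` alongside.
#' * `spearman`: Spearman correlation of each parameter with flexor and
#'   extensor MAS scores per device, after per-stratum IQR screening.
#'
#' Cells whose preconditions fail (for example fewer than 3 pairs) are
#' reported as unavailable rather than dropped. Row order of the input has
#' no effect on any cell.
#'
#' @param trials Data frame with metadata and parameter columns.
#' @param config A [run_config()].
#' @return List of class `study_report` with `icc`, `limbs`, `spearman`
#'   data frames and `bland_altman` scatter data per device x parameter.
#' @export
study_report <- function(trials, config = run_config()) {
  need <- c("subject_id", "limb", "affected", "device", param_cols)
  miss <- setdiff(need, names(trials))
  if (length(miss) > 0) {
    pk_stop(sprintf("trial records lack column(s): %s",
                    paste(miss, collapse = ", ")),
            "pendknee_parameter_error")
  }
  trials <- trials[order(trials$subject_id, trials$limb,
                         trials$device,
                         if (!is.null(trials$trial_index))
                           trials$trial_index else seq_len(nrow(trials))), ]
  devices <- setdiff(unique(trials$device), "goniometer")

  ## Table 1: ICC grid ------------------------------------------------
  icc_rows <- list()
  ba_data <- list()
  for (dev in devices) {
    paired <- pair_with_gonio(trials, dev)
    views <- unique(paired$camera_view)
    strata <- list(overall = rep(TRUE, nrow(paired)))
    for (aff in c(TRUE, FALSE)) {
      lab0 <- if (aff) "affected" else "unaffected"
      if (length(views) > 1) {
        for (v in views) {
          strata[[sprintf("%s (%s)", lab0, v)]] <-
            paired$affected == aff & paired$camera_view == v
        }
      } else {
        strata[[lab0]] <- paired$affected == aff
      }
    }
    for (p in param_cols) {
      for (st in names(strata)) {
        sel <- strata[[st]]
        cell <- icc_cell(paired[[paste0(p, ".gonio")]][sel],
                         paired[[p]][sel])
        icc_rows[[length(icc_rows) + 1]] <-
          cbind(data.frame(device = dev, stratum = st, parameter = p),
                cell)
      }
      ok <- is.finite(paired[[paste0(p, ".gonio")]]) &
            is.finite(paired[[p]])
      if (sum(ok) >= 3) {
        ba <- bland_altman(paired[[paste0(p, ".gonio")]][ok],
                           paired[[p]][ok])
        ba_data[[paste(dev, p, sep = ".")]] <- data.frame(
          device = dev, parameter = p,
          mean = ba$mean, difference = ba$difference,
          stratum = ifelse(paired$affected[ok], "affected", "unaffected"))
      }
    }
  }
  icc_tab <- if (length(icc_rows)) do.call(rbind, icc_rows) else
    data.frame()

  ## Table 2: paired limb comparison ----------------------------------
  limb_rows <- list()
  for (dev in unique(trials$device)) {
    sub <- trials[trials$device == dev, ]
    for (p in param_cols) {
      agg <- stats::aggregate(sub[[p]],
                              by = list(subject_id = sub$subject_id,
                                        affected = sub$affected),
                              FUN = function(v) mean(v[is.finite(v)]))
      wide <- merge(agg[agg$affected, c("subject_id", "x")],
                    agg[!agg$affected, c("subject_id", "x")],
                    by = "subject_id", suffixes = c(".aff", ".unaff"))
      wide <- wide[is.finite(wide$x.aff) & is.finite(wide$x.unaff), ]
      if (nrow(wide) < 3) {
        limb_rows[[length(limb_rows) + 1]] <- data.frame(
          device = dev, parameter = p, mean_affected = NA_real_,
          sd_affected = NA_real_, mean_unaffected = NA_real_,
          sd_unaffected = NA_real_, effect = NA_real_,
          d_paired = NA_real_, t_stat = NA_real_, p_value = NA_real_,
          n = nrow(wide), note = "unavailable (n < 3)")
        next
      }
      pc <- paired_limb_comparison(wide$x.aff, wide$x.unaff)
      limb_rows[[length(limb_rows) + 1]] <- data.frame(
        device = dev, parameter = p,
        mean_affected = pc$mean_a, sd_affected = pc$sd_a,
        mean_unaffected = pc$mean_b, sd_unaffected = pc$sd_b,
        effect = pc$mean_diff, d_paired = pc$d_paired,
        t_stat = pc$t_stat, p_value = pc$p_value, n = pc$n, note = "")
    }
  }
  limb_tab <- do.call(rbind, limb_rows)

  ## Table 3: Spearman vs MAS -----------------------------------------
  sp_rows <- list()
  has_mas <- all(c("mas_flexor", "mas_extensor") %in% names(trials))
  if (has_mas) {
    for (dev in unique(trials$device)) {
      sub <- trials[trials$device == dev, ]
      for (muscle in c("flexors", "extensors")) {
        mas <- if (muscle == "flexors") sub$mas_flexor else
          sub$mas_extensor
        for (p in param_cols) {
          v <- sub[[p]]
          ok <- is.finite(v) & is.finite(mas)
          row <- if (sum(ok) >= 5) {
            cr <- spearman_mas(v[ok], mas[ok])
            data.frame(rho = cr$rho, p_value = cr$p_value,
                       n_used = cr$n_used, n_removed = cr$n_removed,
                       note = if (cr$degenerate) "all MAS tied" else "")
          } else {
            data.frame(rho = NA_real_, p_value = NA_real_,
                       n_used = sum(ok), n_removed = 0L,
                       note = "unavailable (n < 5)")
          }
          sp_rows[[length(sp_rows) + 1]] <-
            cbind(data.frame(device = dev, muscle = muscle,
                             parameter = p), row)
        }
      }
    }
  }
  sp_tab <- if (length(sp_rows)) do.call(rbind, sp_rows) else data.frame()

  structure(list(icc = icc_tab, limbs = limb_tab, spearman = sp_tab,
                 bland_altman = ba_data),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>\n ICC grid:\n")
  print(x$icc, digits = 3)
  cat(" Limb comparison:\n")
  print(x$limbs, digits = 3)
  if (nrow(x$spearman) > 0) {
    cat(" Spearman vs MAS:\n")
    print(x$spearman, digits = 3)
  }
  invisible(x)
}

#' Write study tables to CSV and JSON
#'
#' Emits `table1_icc`, `table2_limbs`, `table3_spearman` (each as `.csv`
#' and `.json`) plus one Bland-Altman scatter CSV per device x parameter.
#'
#' @param report A [study_report()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_study_tables <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  emit <- function(df, stem) {
    pc <- file.path(dir, paste0(stem, ".csv"))
    pj <- file.path(dir, paste0(stem, ".json"))
    utils::write.csv(df, pc, row.names = FALSE)
    jsonlite::write_json(df, pj, dataframe = "rows", digits = NA,
                         na = "null")
    c(pc, pj)
  }
  files <- c(files, emit(report$icc, "table1_icc"))
  files <- c(files, emit(report$limbs, "table2_limbs"))
  files <- c(files, emit(report$spearman, "table3_spearman"))
  for (nm in names(report$bland_altman)) {
    p <- file.path(dir, sprintf("bland_altman_%s.csv",
                                gsub("\\.", "_", nm)))
    utils::write.csv(report$bland_altman[[nm]], p, row.names = FALSE)
    files <- c(files, p)
  }
  invisible(files)
}

#' Between-limb effects from published group means
#'
#' Worked-example form of the limb-comparison report: given a summary
#' table of group means by device and parameter, computes the `effect`
#' column as the raw mean difference
#' `mean_affected - mean_unaffected` -- the convention used in the
#' clinical summary tables this reporting reproduces.
#'
#' @param summary_df Data frame with columns `device`, `parameter`,
#'   `mean_affected`, `mean_unaffected` (defaults to the packaged
#'   reference summary of a 20-patient clinical validation cohort,
#'   `clinical_limb_summary()`).
#' @return The input with an `effect` column appended.
#' @export
limb_effect_table <- function(summary_df = clinical_limb_summary()) {
  need <- c("device", "parameter", "mean_affected", "mean_unaffected")
  if (!all(need %in% names(summary_df))) {
    pk_stop(sprintf("summary table needs columns %s",
                    paste(need, collapse = ", ")),
            "pendknee_parameter_error")
  }
  summary_df$effect <- summary_df$mean_affected -
    summary_df$mean_unaffected
  summary_df
}

#' Reference clinical summary statistics
#'
#' Published group summaries (means and SDs of P1, P2, P3 by measurement
#' device and limb status, with reported paired-test p-values) from a
#' 20-patient clinical validation cohort of the pose-estimation pendulum
#' test. Shipped so the between-limb effect computation can be
#' demonstrated and checked against printed values without access to
#' individual-level recordings.
#'
#' @return Data frame with columns `device`, `parameter`,
#'   `mean_affected`, `sd_affected`, `mean_unaffected`, `sd_unaffected`,
#'   `reported_effect`, `reported_p`.
#' @export
clinical_limb_summary <- function() {
  path <- system.file("extdata", "clinical_limb_summary.csv",
                      package = "pendknee", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
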