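#' Default end-to-end run configuration
#'
#' The defaults reproduce the reference parameter set of the pipeline:
#' 10 fps video, head threshold 1 SD above the bottom 95% of speeds and
#' tail threshold 3 SD above the bottom 99%, a 0.7 s bout-termination
#' gap, peri-event baseline -5 to -3 s, post-onset analysis window
#' 0-5 s, and a 2.91 Z transient threshold.
#'
#' @param ... named overrides merged (recursively) into the defaults.
#' @return list of class `run_config`.
#' @export
default_run_config <- function(...) {
  cfg <- list(
    fps = 10,
    gap_s = 0.7,
    mobility = list(head_fiber = list(q = 0.95, k = 1),
                    tail_tip = list(q = 0.99, k = 3),
                    method = "mean_sd"),
    baseline = list(lambda = 5e4, diff_order = 1L, max_iter = 50L,
                    conv = 0.001),
    z_threshold = 2.91,
    min_samples = 1L,
    peri = list(window = c(-5, 10), baseline = c(-5, -3),
                windows = list(post = c(0, 5), pre = c(-3, 0)),
                offset_s = 0),
    sensor_mode = "dual",
    seed = 1L
  )
  over <- list(...)
  if (length(over)) cfg <- utils::modifyList(cfg, over)
  validate_run_config(cfg)
  structure(cfg, class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Values in the file override the defaults of [default_run_config()];
#' the merged configuration is validated.
#'
#' @param path YAML file.
#' @return a validated `run_config`.
#' @export
read_run_config <- function(path) {
  over <- yaml::read_yaml(path)
  cfg <- utils::modifyList(unclass(default_run_config()), over)
  validate_run_config(cfg)
  structure(cfg, class = "run_config")
}

#' Validate a run configuration
#'
#' @param cfg configuration list.
#' @return the configuration, invisibly, or an error describing the first
#'   invalid field.
#' @export
validate_run_config <- function(cfg) {
  if (!is.numeric(cfg$fps) || cfg$fps <= 0)
    stopf("fps must be > 0", class = "strugglescope_config_error")
  if (cfg$gap_s < 1 / cfg$fps)
    stopf("gap_s below one frame", class = "strugglescope_config_error")
  for (nm in c("head_fiber", "tail_tip")) {
    pc <- cfg$mobility[[nm]]
    if (is.null(pc) || pc$q <= 0 || pc$q > 1 || pc$k < 0)
      stopf("invalid mobility config for %s", nm,
            class = "strugglescope_config_error")
  }
  if (cfg$baseline$lambda <= 0)
    stopf("baseline lambda must be > 0", class = "strugglescope_config_error")
  if (cfg$z_threshold <= 0)
    stopf("z_threshold must be > 0", class = "strugglescope_config_error")
  if (!cfg$sensor_mode %in% c("dual", "single"))
    stopf("sensor_mode must be 'dual' or 'single'",
          class = "strugglescope_config_error")
  pw <- cfg$peri
  if (pw$baseline[2] > 0 || pw$baseline[1] < pw$window[1])
    stopf("invalid peri-event baseline window",
          class = "strugglescope_config_error")
  invisible(cfg)
}

.peri_cfg <- function(cfg) {
  peri_event_config(window = cfg$peri$window, baseline = cfg$peri$baseline,
                    windows = cfg$peri$windows, offset_s = cfg$peri$offset_s)
}

.mob_cfg <- function(cfg) {
  m <- cfg$mobility
  method <- m$method %||% "mean_sd"
  m$method <- NULL
  attr(m, "method") <- method
  m
}

#' Run the full single-session pipeline
#'
#' Executes kinematics -> bout segmentation -> photometry processing ->
#' peri-event alignment -> session statistics, and optionally writes the
#' five session artifacts (bout table, transient table, aligned matrix,
#' bout metrics, stats report) as delimited text. Every report embeds the
#' fully resolved configuration.
#'
#' @param pose a [pose_track()] or path to a pose table.
#' @param photometry a [photometry_recording()] or path to a photometry
#'   table; `NULL` runs the behavior-only pipeline.
#' @param cfg a `run_config` (default [default_run_config()]).
#' @param out_dir optional output directory for the artifact files.
#' @param session_id label for exports.
#' @return list of class `session_report` with elements `bouts`,
#'   `bout_summary`, `photometry`, `aligned`, `metrics`, `stats`,
#'   `config`, `offset_control` (TRUE when `peri$offset_s != 0`).
#' @export
run_session <- function(pose, photometry = NULL, cfg = default_run_config(),
                        out_dir = NULL, session_id = "session") {
  validate_run_config(cfg)
  if (is.character(pose)) pose <- read_pose_table(pose, fps = cfg$fps)
  if (is.character(photometry)) photometry <- read_photometry_table(photometry)
  speeds <- compute_speeds(pose)
  mob <- classify_mobility(speeds, .mob_cfg(cfg))
  bouts <- segment_bouts(mob, gap_s = cfg$gap_s, session_id = session_id)
  report <- list(
    bouts = bouts,
    bout_summary = summarize_bouts(bouts),
    mobility_thresholds = mob$thresholds,
    photometry = NULL, aligned = NULL, metrics = NULL, stats = NULL,
    offset_control = cfg$peri$offset_s != 0,
    config = cfg,
    session_id = session_id
  )
  if (!is.null(photometry)) {
    proc <- process_photometry(photometry, mode = cfg$sensor_mode,
                               baseline = cfg$baseline,
                               z_threshold = cfg$z_threshold,
                               min_samples = cfg$min_samples)
    aligned <- align_to_events(proc$z, bouts, .peri_cfg(cfg))
    metrics <- bout_metrics(aligned)
    ok <- metrics[!metrics$excluded, , drop = FALSE]
    stats_out <- list(transient_frequency_hz = proc$frequency_hz)
    if (nrow(ok) >= 3L && stats::sd(ok$duration_s) > 0 &&
        stats::sd(ok$auc_post) > 0) {
      stats_out$auc_duration <- correlate_auc_duration(ok)
      stats_out$positive_auc <- positive_auc_proportion(ok)
    }
    report$photometry <- proc
    report$aligned <- aligned
    report$metrics <- metrics
    report$stats <- stats_out
  }
  class(report) <- "session_report"
  if (!is.null(out_dir)) .write_session_artifacts(report, out_dir)
  report
}

.write_session_artifacts <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_bout_table(report$bouts, file.path(out_dir, "bouts.csv"))
  if (!is.null(report$photometry)) {
    write_transient_table(report$photometry$transients,
                          file.path(out_dir, "transients.csv"))
    write_aligned_matrix(report$aligned,
                         file.path(out_dir, "aligned_matrix.csv"))
    utils::write.csv(report$metrics, file.path(out_dir, "metrics.csv"),
                     row.names = FALSE)
    st <- report$stats
    rows <- data.frame(key = "transient_frequency_hz",
                       value = st$transient_frequency_hz)
    if (!is.null(st$auc_duration)) {
      cr <- st$auc_duration
      rows <- rbind(rows, data.frame(
        key = c("pearson_r", "pearson_p", "slope", "slope_ci_lower",
                "slope_ci_upper", "n_bouts", "positive_auc_p"),
        value = c(cr$r, cr$p, cr$slope, cr$slope_ci[["lower"]],
                  cr$slope_ci[["upper"]], cr$n, st$positive_auc$p)))
    }
    utils::write.csv(rows, file.path(out_dir, "stats.csv"),
                     row.names = FALSE)
  }
  yaml::write_yaml(list(config = unclass(report$config),
                        session_id = report$session_id,
                        offset_control = report$offset_control),
                   file.path(out_dir, "run_config.yaml"))
  invisible(out_dir)
}

#' Run the multi-day study pipeline
#'
#' Processes every subject-day session (missing cells are logged and
#' skipped), then assembles the study-level tables: per-day pooled
#' AUC-duration correlations with slopes and 95% CIs, per-subject
#' transient frequencies normalized to day 1, per-day full-body bout
#' counts, and a monotone-trend flag on the recovered slopes (Spearman
#' rho of slope against day).
#'
#' @param study nested list `study[[subject]][[day]]`, each cell holding
#'   `pose` and `photometry` entries as produced by [simulate_study()]
#'   (or lists with `track`/`recording` objects read from disk).
#' @param cfg a `run_config`.
#' @return list of class `study_report`: `per_day_correlations`,
#'   `frequencies`, `bout_counts`, `slope_trend_rho`,
#'   `habituation_flagged`, `config`.
#' @export
run_study <- function(study, cfg = default_run_config()) {
  validate_run_config(cfg)
  metrics_all <- list()
  freq_rows <- list()
  bout_tables <- list()
  for (subj in names(study)) {
    bout_tables[[subj]] <- list()
    for (day in names(study[[subj]])) {
      cell <- study[[subj]][[day]]
      if (is.null(cell)) {
        message(sprintf("missing session: %s day %s", subj, day))
        next
      }
      rep1 <- run_session(cell$pose$track, cell$photometry$recording, cfg,
                          session_id = sprintf("%s_day%s", subj, day))
      bout_tables[[subj]][[day]] <- rep1$bouts
      m <- rep1$metrics
      if (!is.null(m)) {
        m$subject <- subj
        m$day <- as.integer(day)
        metrics_all[[length(metrics_all) + 1L]] <- m
      }
      freq_rows[[length(freq_rows) + 1L]] <- data.frame(
        subject = subj, day = as.integer(day),
        freq_hz = rep1$stats$transient_frequency_hz %||% NA_real_)
    }
  }
  metrics <- do.call(rbind, metrics_all)
  per_day <- NULL
  if (!is.null(metrics)) {
    days <- sort(unique(metrics$day))
    per_day <- do.call(rbind, lapply(days, function(d) {
      ok <- metrics[metrics$day == d & !metrics$excluded, , drop = FALSE]
      if (nrow(ok) < 3L || stats::sd(ok$duration_s) == 0)
        return(data.frame(day = d, n = nrow(ok), r = NA, p = NA, slope = NA,
                          ci_lower = NA, ci_upper = NA))
      cr <- correlate_auc_duration(ok)
      data.frame(day = d, n = cr$n, r = cr$r, p = cr$p, slope = cr$slope,
                 ci_lower = cr$slope_ci[["lower"]],
                 ci_upper = cr$slope_ci[["upper"]])
    }))
  }
  freqs <- do.call(rbind, freq_rows)
  norm <- if (!is.null(freqs)) normalize_frequency_by_day(freqs) else NULL
  counts <- count_bouts_by_day(bout_tables)
  rho <- NA_real_
  if (!is.null(per_day) && sum(!is.na(per_day$slope)) >= 3L)
    rho <- suppressWarnings(
      stats::cor(per_day$day, per_day$slope, method = "spearman",
                 use = "complete.obs"))
  structure(
    list(per_day_correlations = per_day,
         frequencies = norm,
         bout_counts = counts,
         metrics = metrics,
         slope_trend_rho = rho,
         habituation_flagged = is.finite(rho) && rho <= -0.5,
         config = cfg),
    class = "study_report"
  )
}
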