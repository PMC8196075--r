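#' Peri-event window configuration
#'
#' @param window relative-time span (s) extracted around each onset;
#'   default -5 to +10.
#' @param baseline window (s) whose mean and sd standardize each row;
#'   default -5 to -3, fully preceding onset.
#' @param windows named list of analysis windows; defaults `post` = 0-5 s
#'   after onset (metrics are computed over the fixed 5 s following onset
#'   regardless of bout length) and `pre` = -3-0 s preceding it.
#' @param offset_s artificial shift of the behavior-photometry time lock,
#'   in seconds. 0 for real analyses; +10 is the negative control that
#'   destroys the association between bouts and bout-locked signals.
#' @return list of class `peri_event_config`.
#' @export
peri_event_config <- function(window = c(-5, 10), baseline = c(-5, -3),
                              windows = list(post = c(0, 5), pre = c(-3, 0)),
                              offset_s = 0) {
  stopifnot(length(window) == 2L, window[1] < window[2])
  if (baseline[2] > 0)
    stopf("baseline window must precede onset")
  if (baseline[1] < window[1] || baseline[2] > window[2])
    stopf("baseline window must lie inside the peri-event window")
  for (w in windows)
    if (w[1] < window[1] || w[2] > window[2])
      stopf("analysis windows must lie inside the peri-event window")
  structure(list(window = window, baseline = baseline, windows = windows,
                 offset_s = offset_s),
            class = "peri_event_config")
}

#' Align a session trace to bout onsets
#'
#' Extracts the trace over `[onset + offset_s + window]` for every bout
#' and standardizes each row against its own baseline window
#' (`zscore_peri_event()`). Rows are mapped onto a common relative-time
#' grid with step equal to the trace sample period by nearest-sample
#' indexing (no interpolation). Bouts whose window falls outside the
#' recording, or whose baseline has zero variance, are retained in the
#' output but flagged excluded with a reason, never dropped silently.
#'
#' @param trace data frame with a time column and a value column (e.g. the
#'   `z` element of [process_photometry()], or a `dff_trace`).
#' @param bouts a `bout_table` sharing the session time base.
#' @param cfg a [peri_event_config()].
#' @return list of class `event_aligned_matrix`: `z` (events x time
#'   matrix, NA rows for excluded events), `time` (relative-time grid),
#'   `events` (per-bout data frame with `excluded`, `reason`), `cfg`.
#' @export
align_to_events <- function(trace, bouts, cfg = peri_event_config()) {
  stopifnot(inherits(cfg, "peri_event_config"))
  tt <- trace[[1L]]
  vv <- trace[[2L]]
  fs <- 1 / stats::median(diff(tt))
  grid <- seq(cfg$window[1L], cfg$window[2L], by = 1 / fs)
  nb <- nrow(bouts)
  zmat <- matrix(NA_real_, nb, length(grid))
  excluded <- logical(nb)
  reason <- rep(NA_character_, nb)
  n <- length(tt)
  for (i in seq_len(nb)) {
    center <- bouts$onset_s[i] + cfg$offset_s
    idx <- as.integer(round((center + grid - tt[1L]) * fs)) + 1L
    if (idx[1L] < 1L || idx[length(idx)] > n) {
      excluded[i] <- TRUE
      reason[i] <- "window_out_of_range"
      next
    }
    row <- vv[idx]
    zr <- zscore_peri_event(row, grid, cfg)
    if (is.null(zr)) {
      excluded[i] <- TRUE
      reason[i] <- "degenerate_baseline"
      next
    }
    zmat[i, ] <- zr
  }
  if (all(excluded))
    warning("no events retained in the aligned matrix")
  events <- data.frame(
    bout = if (nb) (bouts$bout %||% seq_len(nb)) else integer(),
    onset_s = if (nb) bouts$onset_s else numeric(),
    duration_s = if (nb) bouts$duration_s else numeric(),
    type = if (nb) bouts$type else character(),
    excluded = excluded, reason = reason,
    stringsAsFactors = FALSE
  )
  structure(list(z = zmat, time = grid, events = events, cfg = cfg,
                 sample_rate = fs),
            class = "event_aligned_matrix")
}

#' Baseline-window Z-scoring of one aligned row
#'
#' Time-locked Z: `(x[t] - mean(baseline samples)) / sd(baseline
#' samples)`, with the baseline taken from the pre-onset window of the
#' configuration (default -5 to -3 s) and sd using the n-1 denominator.
#'
#' @param row numeric aligned trace on the grid `grid`.
#' @param grid relative times (s) for `row`.
#' @param cfg a [peri_event_config()].
#' @return the Z-scored row, or `NULL` if the baseline sd is zero or the
#'   baseline window holds fewer than 2 samples.
#' @export
zscore_peri_event <- function(row, grid, cfg = peri_event_config()) {
  sel <- grid >= cfg$baseline[1L] - 1e-9 & grid <= cfg$baseline[2L] + 1e-9
  b <- row[sel]
  if (length(b) < 2L) return(NULL)
  s <- stats::sd(b)
  if (!is.finite(s) || s == 0) return(NULL)
  (row - mean(b)) / s
}

#' Signed trapezoidal AUC of an aligned row over a window
#'
#' Negative deflections yield negative area, as required for sensors
#' reporting decreases (e.g. GABA sensors).
#'
#' @param z numeric row on grid `grid`.
#' @param grid relative times (s).
#' @param window length-2 numeric window (s), inclusive.
#' @return area in Z*s.
#' @export
compute_auc <- function(z, grid, window) {
  sel <- grid >= window[1L] - 1e-9 & grid <= window[2L] + 1e-9
  if (!any(sel)) stopf("window outside the grid")
  trapz(grid[sel], z[sel])
}

#' Maximum (signed) value of an aligned row over a window
#'
#' @inheritParams compute_auc
#' @return maximum Z in the window; may be negative.
#' @export
compute_max_peak <- function(z, grid, window) {
  sel <- grid >= window[1L] - 1e-9 & grid <= window[2L] + 1e-9
  if (!any(sel)) stopf("window outside the grid")
  max(z[sel])
}

#' Per-bout AUC and peak metrics
#'
#' Computes the signed AUC and maximum peak over each named analysis
#' window of the configuration for every retained row, plus the
#' positive-transient indicators (`auc_positive` iff post-window AUC > 0,
#' likewise `peak_positive`).
#'
#' @param aligned an `event_aligned_matrix` from [align_to_events()].
#' @return data frame with one row per event: `bout`, `duration_s`,
#'   `type`, `excluded`, then `auc_<w>`/`peak_<w>` per window, and the
#'   positivity flags for the `post` window.
#' @export
bout_metrics <- function(aligned) {
  stopifnot(inherits(aligned, "event_aligned_matrix"))
  ev <- aligned$events
  out <- ev[, c("bout", "onset_s", "duration_s", "type", "excluded")]
  for (wn in names(aligned$cfg$windows)) {
    w <- aligned$cfg$windows[[wn]]
    auc <- peak <- rep(NA_real_, nrow(ev))
    for (i in which(!ev$excluded)) {
      auc[i] <- compute_auc(aligned$z[i, ], aligned$time, w)
      peak[i] <- compute_max_peak(aligned$z[i, ], aligned$time, w)
    }
    out[[paste0("auc_", wn)]] <- auc
    out[[paste0("peak_", wn)]] <- peak
  }
  if ("auc_post" %in% names(out)) {
    out$auc_positive <- out$auc_post > 0
    out$peak_positive <- out$peak_post > 0
  }
  out
}

#' Heatmap and mean trace of an aligned matrix
#'
#' Rows are ordered by subject/grouping blocks when a grouping vector is
#' given. Values are clipped to the color limits for display only; all
#' metrics are computed on the unclipped matrix. The companion mean trace
#' carries the per-timepoint s.e.m. across bouts.
#'
#' @param aligned an `event_aligned_matrix`.
#' @param clip length-2 color limits; values beyond them are displayed at
#'   the limit color.
#' @param group optional per-event grouping (e.g. subject ids) used to
#'   order rows into blocks.
#' @return list with `mean_trace` (data frame time/mean/sem/n), `plot`
#'   (a ggplot raster), and `order` (row order used).
#' @export
build_heatmap <- function(aligned, clip = c(-3, 3), group = NULL) {
  stopifnot(inherits(aligned, "event_aligned_matrix"))
  keep <- which(!aligned$events$excluded)
  if (!length(keep)) stopf("no retained rows to plot")
  ord <- if (is.null(group)) keep else keep[order(group[keep])]
  z <- aligned$z[ord, , drop = FALSE]
  m <- colMeans(z)
  sem <- apply(z, 2L, function(col)
    if (length(col) > 1L) stats::sd(col) / sqrt(length(col)) else 0)
  mean_trace <- data.frame(time = aligned$time, mean = m, sem = sem,
                           n = nrow(z))
  zc <- pmin(pmax(z, clip[1L]), clip[2L])
  df <- data.frame(
    time = rep(aligned$time, each = nrow(zc)),
    event = rep(seq_len(nrow(zc)), times = ncol(zc)),
    z = as.vector(zc)
  )
  plt <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$event,
                                          fill = .data$z)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                                  limits = clip, name = "Z") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "Time from bout onset (s)", y = "Bout") +
    ggplot2::theme_minimal()
  list(mean_trace = mean_trace, plot = plt, order = ord)
}

#' Export an aligned matrix as delimited text
#'
#' One row per bout; header gives the relative times of the grid.
#'
#' @param aligned an `event_aligned_matrix`.
#' @param path output CSV path.
#' @export
write_aligned_matrix <- function(aligned, path) {
  m <- as.data.frame(aligned$z)
  names(m) <- sprintf("t_%.3f", aligned$time)
  out <- cbind(aligned$events[, c("bout", "onset_s", "duration_s", "type",
                                  "excluded")], m)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
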