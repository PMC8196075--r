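#' Detect threshold transients in a standardized trace
#'
#' A single transient is the maximal run of consecutive samples with
#' `Z >= z_threshold`: it starts when a data point at or above threshold
#' is detected and ends just before the next data point below threshold.
#' The default threshold of 2.91 Z marks points that are statistical
#' outliers from baseline. Each transient carries its maximum peak
#' amplitude (the maximum Z during the run) and its trapezoidal area
#' (Z\\*s; 0 for single-sample runs).
#'
#' @param z numeric standardized series.
#' @param time sample times in seconds (same length as `z`); alternatively
#'   supply `fs` and times `0, 1/fs, ...` are used.
#' @param fs sample rate in Hz, used only when `time` is missing.
#' @param z_threshold detection threshold in Z units (default 2.91).
#' @param min_samples minimum run length to report (default 1).
#' @return a `transient_table`: data frame with columns `start_s`,
#'   `end_s`, `max_peak_z`, `area`, `n_samples`.
#' @export
detect_transients <- function(z, time = NULL, fs = NULL, z_threshold = 2.91,
                              min_samples = 1L) {
  if (any(!is.finite(z))) stopf("`z` must be finite")
  if (z_threshold <= 0) stopf("`z_threshold` must be > 0")
  if (is.null(time)) {
    if (is.null(fs)) stopf("supply `time` or `fs`")
    time <- (seq_along(z) - 1L) / fs
  }
  above <- z >= z_threshold
  empty <- data.frame(start_s = numeric(), end_s = numeric(),
                      max_peak_z = numeric(), area = numeric(),
                      n_samples = integer())
  if (!any(above))
    return(structure(empty, class = c("transient_table", "data.frame")))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_samples
  starts <- starts[keep]; ends <- ends[keep]
  if (!length(starts))
    return(structure(empty, class = c("transient_table", "data.frame")))
  out <- data.frame(
    start_s = time[starts],
    end_s = time[ends],
    max_peak_z = vapply(seq_along(starts), function(i)
      max(z[starts[i]:ends[i]]), numeric(1)),
    area = vapply(seq_along(starts), function(i)
      trapz(time[starts[i]:ends[i]], z[starts[i]:ends[i]]), numeric(1)),
    n_samples = ends - starts + 1L
  )
  structure(out, class = c("transient_table", "data.frame"))
}

#' Transient frequency
#'
#' Number of transients per second (Hz).
#'
#' @param transients a `transient_table` from [detect_transients()].
#' @param duration_s session duration in seconds (> 0).
#' @return frequency in Hz.
#' @export
transient_frequency <- function(transients, duration_s) {
  if (duration_s <= 0) stopf("`duration_s` must be > 0")
  nrow(transients) / duration_s
}

#' Export a transient table
#'
#' @param transients a `transient_table`.
#' @param path output CSV path.
#' @export
write_transient_table <- function(transients, path) {
  utils::write.csv(
    transients[, c("start_s", "end_s", "max_peak_z", "area")],
    path, row.names = FALSE)
  invisible(path)
}
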