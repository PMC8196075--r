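#' Construct a photometry recording
#'
#' Holds a uniformly sampled fluorescence signal channel (470 nm
#' excitation) and, for calcium-indicator recordings, the isosbestic
#' reference channel (405 nm excitation), at which the indicator's
#' fluorescence is calcium-independent.
#'
#' @param time sample times in seconds, strictly increasing and uniform
#'   to within 1%.
#' @param signal signal-channel fluorescence (a.u.), same length as `time`.
#' @param reference optional reference-channel fluorescence (a.u.);
#'   single-channel sensors (e.g. glutamate/GABA sensors) omit it.
#' @return object of class `photometry_recording` with derived
#'   `sample_rate`.
#' @export
photometry_recording <- function(time, signal, reference = NULL) {
  n <- length(time)
  if (n < 2L) stopf("need at least 2 samples")
  if (length(signal) != n)
    stopf("signal and time lengths differ", class = "strugglescope_format_error")
  if (!is.null(reference) && length(reference) != n)
    stopf("reference and time lengths differ", class = "strugglescope_format_error")
  dt <- diff(time)
  if (any(dt <= 0))
    stopf("time must be strictly increasing (repeated or reversed timestamps)",
          class = "strugglescope_format_error")
  med <- stats::median(dt)
  if (any(abs(dt - med) > 0.01 * med))
    stopf("sampling is non-uniform beyond 1%% tolerance",
          class = "strugglescope_format_error")
  structure(
    list(time = as.numeric(time), signal = as.numeric(signal),
         reference = if (is.null(reference)) NULL else as.numeric(reference),
         sample_rate = 1 / med),
    class = "photometry_recording"
  )
}

#' @export
print.photometry_recording <- function(x, ...) {
  cat(sprintf("<photometry_recording> %d samples @ %.4g Hz (%.1f s), %s\n",
              length(x$time), x$sample_rate, diff(range(x$time)),
              if (is.null(x$reference)) "single-channel" else "dual-channel"))
  invisible(x)
}

#' Read a photometry table
#'
#' Reads delimited text with a time column plus one or two channel columns
#' (`time_s, ch470[, ch405]`; any names are accepted in that order).
#' Optionally decimates to a lower target rate by block averaging, which
#' acts as an anti-alias smoother and preserves the trace mean.
#'
#' @param path delimited-text file.
#' @param decimate_to optional target sample rate in Hz.
#' @param sep field separator.
#' @return a [photometry_recording()].
#' @export
read_photometry_table <- function(path, decimate_to = NULL, sep = ",") {
  if (!file.exists(path)) stopf("file not found: %s", path)
  tab <- utils::read.table(path, sep = sep, header = TRUE)
  if (ncol(tab) < 2L)
    stopf("need a time column plus at least one channel",
          class = "strugglescope_format_error")
  rec <- photometry_recording(
    time = tab[[1L]], signal = tab[[2L]],
    reference = if (ncol(tab) >= 3L) tab[[3L]] else NULL
  )
  if (!is.null(decimate_to)) rec <- decimate_recording(rec, decimate_to)
  rec
}

#' Decimate a recording by block averaging
#'
#' @param rec a [photometry_recording()].
#' @param target_rate target sample rate (Hz); the decimation factor is
#'   `round(sample_rate / target_rate)` and trailing samples that do not
#'   fill a block are dropped.
#' @return a decimated [photometry_recording()].
#' @export
decimate_recording <- function(rec, target_rate) {
  stopifnot(inherits(rec, "photometry_recording"))
  fac <- max(1L, as.integer(round(rec$sample_rate / target_rate)))
  if (fac == 1L) return(rec)
  n <- (length(rec$time) %/% fac) * fac
  blocks <- rep(seq_len(n %/% fac), each = fac)
  avg <- function(v) as.numeric(tapply(v[seq_len(n)], blocks, mean))
  photometry_recording(
    time = avg(rec$time), signal = avg(rec$signal),
    reference = if (is.null(rec$reference)) NULL else avg(rec$reference)
  )
}

#' Fit the reference channel to the signal channel
#'
#' Ordinary least-squares regression of the 470 nm signal on the 405 nm
#' isosbestic reference over the whole session. The fitted reference
#' captures bleaching drift and motion artifact shared by both channels.
#'
#' @param rec a dual-channel [photometry_recording()].
#' @return list of class `isosbestic_fit`: `slope`, `intercept`,
#'   `fitted_reference`.
#' @export
fit_isosbestic <- function(rec) {
  stopifnot(inherits(rec, "photometry_recording"))
  if (is.null(rec$reference))
    stopf("recording has no reference channel")
  if (stats::sd(rec$reference) == 0)
    stopf("constant reference channel", class = "strugglescope_degenerate_fit")
  fit <- stats::lm.fit(cbind(1, rec$reference), rec$signal)
  slope <- unname(fit$coefficients[2L])
  intercept <- unname(fit$coefficients[1L])
  structure(
    list(slope = slope, intercept = intercept,
         fitted_reference = intercept + slope * rec$reference),
    class = "isosbestic_fit"
  )
}

#' Fractional fluorescence change (dF/F)
#'
#' `dff[t] = (signal[t] - fitted_reference[t]) / fitted_reference[t]`,
#' the standard isosbestic-corrected fractional change of the
#' indicator-mediated signal relative to the fitted reference.
#'
#' @param rec a [photometry_recording()].
#' @param fit an `isosbestic_fit` from [fit_isosbestic()], or any numeric
#'   baseline vector of matching length (used as F0 for single-channel
#'   sensors).
#' @return a `dff_trace`: data frame with columns `time`, `dff`.
#' @export
compute_dff <- function(rec, fit) {
  stopifnot(inherits(rec, "photometry_recording"))
  f0 <- if (inherits(fit, "isosbestic_fit")) fit$fitted_reference else as.numeric(fit)
  if (length(f0) != length(rec$signal))
    stopf("baseline length differs from recording length")
  bad <- which(f0 <= 0)
  if (length(bad))
    stopf("fitted reference is non-positive at sample %d (t = %.3f s)",
          bad[1L], rec$time[bad[1L]], class = "strugglescope_domain_error")
  structure(
    data.frame(time = rec$time, dff = (rec$signal - f0) / f0),
    class = c("dff_trace", "data.frame"),
    sample_rate = rec$sample_rate
  )
}

#' Session-level Z standardization
#'
#' `(y - mean(y)) / sd(y)` over the whole session (n-1 denominator). This
#' session-level standardization precedes transient detection and is
#' distinct from the peri-event baseline-window Z-scoring of
#' [zscore_peri_event()].
#'
#' @param y numeric series.
#' @return standardized numeric series with mean 0 and sd 1.
#' @export
standardize_trace <- function(y) {
  s <- stats::sd(y)
  if (!is.finite(s) || s == 0)
    stopf("zero-variance trace cannot be standardized",
          class = "strugglescope_degenerate_input")
  (y - mean(y)) / s
}

#' Full photometry processing pipeline
#'
#' Runs reference fit (dual-channel mode) -> dF/F -> airPLS baseline
#' correction -> session Z-scoring -> transient detection. In
#' single-channel mode (sensors without an isosbestic wavelength) the
#' airPLS baseline of the raw signal serves as F0 for dF/F.
#'
#' @param rec a [photometry_recording()].
#' @param mode `"dual"` (isosbestic regression, default when a reference
#'   channel is present) or `"single"`.
#' @param baseline list of airPLS settings, see [airpls_baseline()].
#' @param z_threshold,min_samples transient detection settings, see
#'   [detect_transients()].
#' @return list with `dff`, `corrected` (baseline-subtracted dF/F), `z`
#'   (data frame time/z), `transients`, `frequency_hz`, `fit`, `baseline`.
#' @export
process_photometry <- function(rec, mode = if (is.null(rec$reference)) "single" else "dual",
                               baseline = list(),
                               z_threshold = 2.91, min_samples = 1L) {
  stopifnot(inherits(rec, "photometry_recording"))
  mode <- match.arg(mode, c("dual", "single"))
  bl <- utils::modifyList(
    list(lambda = 5e4, diff_order = 1L, max_iter = 50L, conv = 0.001),
    baseline)
  if (mode == "dual") {
    fit <- fit_isosbestic(rec)
    dff <- compute_dff(rec, fit)
  } else {
    fit <- NULL
    f0 <- airpls_baseline(rec$signal, lambda = bl$lambda,
                          diff_order = bl$diff_order,
                          max_iter = bl$max_iter, conv = bl$conv)
    dff <- compute_dff(rec, f0)
  }
  base <- airpls_baseline(dff$dff, lambda = bl$lambda,
                          diff_order = bl$diff_order,
                          max_iter = bl$max_iter, conv = bl$conv)
  corrected <- dff$dff - base
  z <- standardize_trace(corrected)
  tr <- detect_transients(z, time = rec$time, z_threshold = z_threshold,
                          min_samples = min_samples)
  dur <- diff(range(rec$time)) + 1 / rec$sample_rate
  list(
    dff = dff,
    corrected = corrected,
    z = structure(data.frame(time = rec$time, z = z),
                  sample_rate = rec$sample_rate),
    transients = tr,
    frequency_hz = transient_frequency(tr, dur),
    fit = fit,
    baseline = base
  )
}
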