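#' Behavior simulation parameters
#'
#' Defaults emulate a 30-min restraint exposure filmed at 10 fps with a
#' struggle-bout rate of about one per minute and gamma-distributed bout
#' durations with mean 2 s. Head-only movements are the most frequent
#' type and full-body movements outnumber tail-only ones, mirroring the
#' empirical ordering of bout-type frequencies during restraint.
#'
#' Idle tracking noise is modeled as the characteristic quantization
#' "flicker" of markerless pose estimators on a stationary target: the
#' detected point alternates between two candidate locations
#' `idle_jitter_px` apart (per-frame switch probability
#' `idle_switch_prob`) with a small additive Gaussian component
#' (`idle_noise_sd`). Within a movement epoch the involved points scatter
#' around their anchor with per-axis SD `move_step_px`.
#'
#' @param session_s session length in seconds (default 1800).
#' @param fps frame rate (default 10).
#' @param bout_rate_per_min homogeneous Poisson bout rate (default 1).
#' @param duration_shape,duration_scale gamma parameters of bout duration
#'   in seconds (defaults 2 and 1: mean 2 s).
#' @param type_probs probabilities of head-only, tail-only, full-body
#'   types; must sum to 1.
#' @param idle_jitter_px flicker separation in pixels (default 0.5).
#' @param idle_switch_prob per-frame flicker switch probability (0.7).
#' @param idle_noise_sd additive sub-pixel noise SD (default 0.005 px).
#' @param move_step_px per-axis movement scatter SD (default 4 px).
#' @param min_gap_s bouts closer than this are merged in the ground truth
#'   (default 0.7 s, the contiguity convention).
#' @param seed RNG seed; every generator output is a pure function of
#'   (params, seed).
#' @return list of class `behavior_sim_params`.
#' @export
behavior_sim_params <- function(session_s = 1800, fps = 10,
                                bout_rate_per_min = 1,
                                duration_shape = 2, duration_scale = 1,
                                type_probs = c(head_only = 0.45,
                                               tail_only = 0.20,
                                               full_body = 0.35),
                                idle_jitter_px = 0.5,
                                idle_switch_prob = 0.7,
                                idle_noise_sd = 0.005,
                                move_step_px = 4,
                                min_gap_s = 0.7,
                                seed = 1) {
  stopifnot(session_s > 0, fps > 0, bout_rate_per_min >= 0)
  if (abs(sum(type_probs) - 1) > 1e-9) stopf("type_probs must sum to 1")
  structure(as.list(environment()), class = "behavior_sim_params")
}

# involvement sets per type
.type_points <- function(type) {
  switch(type,
         head_only = c(head = TRUE, tail = FALSE),
         tail_only = c(head = FALSE, tail = TRUE),
         full_body = c(head = TRUE, tail = TRUE))
}

.points_type <- function(head, tail) {
  if (head && tail) "full_body" else if (head) "head_only" else "tail_only"
}

#' Simulate a ground-truth bout schedule
#'
#' Bout onsets follow a homogeneous Poisson process; durations are gamma
#' draws; types are sampled from `type_probs`. Bouts separated by less
#' than `min_gap_s` (or overlapping) are merged, the merged bout taking
#' the union of involved points; a warning is raised if merging removes
#' more than half of the drawn events. Onsets/offsets are reported on the
#' frame grid so that frame-accurate recovery is well defined.
#'
#' @param params a [behavior_sim_params()].
#' @return data frame `onset_s`, `offset_s`, `duration_s`, `type` with
#'   attributes `session_s`, `fps`.
#' @export
simulate_bout_schedule <- function(params) {
  stopifnot(inherits(params, "behavior_sim_params"))
  p <- params
  with_seed(p$seed, {
    n <- stats::rpois(1L, p$bout_rate_per_min * p$session_s / 60)
    if (n == 0L) {
      df <- data.frame(onset_s = numeric(), offset_s = numeric(),
                       duration_s = numeric(), type = character())
      attr(df, "session_s") <- p$session_s
      attr(df, "fps") <- p$fps
      return(df)
    }
    onset <- sort(stats::runif(n, 0, p$session_s - 2))
    dur <- pmin(pmax(stats::rgamma(n, shape = p$duration_shape,
                                   scale = p$duration_scale), 0.2), 30)
    type <- sample(names(p$type_probs), n, replace = TRUE,
                   prob = p$type_probs)
    nf <- round(p$session_s * p$fps)
    onset_f <- pmin(floor(onset * p$fps), nf - 1L)
    nfr <- pmax(1L, as.integer(round(dur * p$fps)))
    offset_f <- pmin(onset_f + nfr - 1L, nf - 1L)
    # merge bouts separated by < min_gap_s (contiguity convention)
    gap_frames <- floor(p$min_gap_s * p$fps + 1e-9)
    keep_on <- onset_f[1L]; keep_off <- offset_f[1L]
    inv <- .type_points(type[1L])
    out <- list()
    n_merged <- 0L
    if (n > 1L) for (i in 2L:n) {
      if (onset_f[i] - keep_off - 1L <= gap_frames) {
        keep_off <- max(keep_off, offset_f[i])
        inv <- inv | .type_points(type[i])
        n_merged <- n_merged + 1L
      } else {
        out[[length(out) + 1L]] <- list(on = keep_on, off = keep_off,
                                        type = .points_type(inv["head"], inv["tail"]))
        keep_on <- onset_f[i]; keep_off <- offset_f[i]
        inv <- .type_points(type[i])
      }
    }
    out[[length(out) + 1L]] <- list(on = keep_on, off = keep_off,
                                    type = .points_type(inv["head"], inv["tail"]))
    if (n_merged > 0.5 * n)
      warning("bout rate so high that merging removed >50% of events")
    df <- data.frame(
      onset_s = vapply(out, function(b) b$on, numeric(1)) / p$fps,
      offset_s = vapply(out, function(b) b$off, numeric(1)) / p$fps,
      type = vapply(out, function(b) b$type, character(1)),
      stringsAsFactors = FALSE
    )
    df$duration_s <- df$offset_s - df$onset_s + 1 / p$fps
    df <- df[, c("onset_s", "offset_s", "duration_s", "type")]
    attr(df, "session_s") <- p$session_s
    attr(df, "fps") <- p$fps
    df
  })
}

#' Simulate a tracked pose session with ground truth
#'
#' Renders head-fiber and tail-tip trajectories for a bout schedule drawn
#' by [simulate_bout_schedule()]: outside bouts each point shows bounded
#' idle flicker; inside a bout the involved point(s) scatter widely around
#' their anchor. Returns the track together with the full ground truth
#' (bout table and per-frame, per-point true mobility).
#'
#' @param params a [behavior_sim_params()].
#' @return list with `track` (a [pose_track()]) and `truth` (list:
#'   `bouts`, `mobile` frames x points logical matrix, `params`).
#' @export
simulate_pose_session <- function(params) {
  stopifnot(inherits(params, "behavior_sim_params"))
  p <- params
  bouts <- simulate_bout_schedule(params)
  nf <- round(p$session_s * p$fps)
  anchors <- list(head_fiber = c(320, 240), tail_tip = c(420, 310))
  truth_mobile <- matrix(FALSE, nf, 2L,
                         dimnames = list(NULL, c("head_fiber", "tail_tip")))
  if (nrow(bouts)) {
    for (i in seq_len(nrow(bouts))) {
      rows <- (round(bouts$onset_s[i] * p$fps) + 1L):(round(bouts$offset_s[i] * p$fps) + 1L)
      inv <- .type_points(bouts$type[i])
      if (inv["head"]) truth_mobile[rows, "head_fiber"] <- TRUE
      if (inv["tail"]) truth_mobile[rows, "tail_tip"] <- TRUE
    }
  }
  positions <- with_seed(p$seed + 1L, {
    lapply(names(anchors), function(nm) {
      anchor <- anchors[[nm]]
      theta <- stats::runif(1, 0, 2 * pi)
      delta <- p$idle_jitter_px * c(cos(theta), sin(theta))
      flick <- cumsum(stats::rbinom(nf, 1L, p$idle_switch_prob)) %% 2L
      x <- anchor[1L] + flick * delta[1L] + stats::rnorm(nf, 0, p$idle_noise_sd)
      y <- anchor[2L] + flick * delta[2L] + stats::rnorm(nf, 0, p$idle_noise_sd)
      mv <- truth_mobile[, nm]
      nmv <- sum(mv)
      if (nmv) {
        x[mv] <- anchor[1L] + stats::rnorm(nmv, 0, p$move_step_px)
        y[mv] <- anchor[2L] + stats::rnorm(nmv, 0, p$move_step_px)
      }
      cbind(x = x, y = y)
    })
  })
  names(positions) <- names(anchors)
  list(
    track = pose_track(positions, fps = p$fps),
    truth = list(bouts = bouts, mobile = truth_mobile, params = params)
  )
}

#' Photometry simulation parameters
#'
#' Defaults emulate a two-channel recording acquired at 1 kHz and
#' analyzed at 20 Hz: the generator draws channels directly on the 20 Hz
#' grid with the white-noise SD scaled by `sqrt(sample_rate / acq_rate)`,
#' which is exactly the distribution of block-averaged acquisition noise.
#' Each channel bleaches with its own exponential time constant (so the
#' isosbestic regression has real work to do), both share a slow motion
#' artifact, and the indicator signal is a sum of fast-rise/slow-decay
#' double-exponential kernels whose amplitude grows with bout duration at
#' rate `coupling_beta` (fractional dF/F per second of struggle).
#'
#' @param sample_rate analysis rate, Hz (default 20).
#' @param acq_rate nominal acquisition rate, Hz (default 1000).
#' @param noise_sd white noise SD per acquisition sample, a.u. (default 1).
#' @param b0_470,b0_405 initial channel intensities, a.u.
#' @param bleach_tau_470,bleach_tau_405 bleaching time constants, s.
#' @param kernel_rise,kernel_decay transient kernel time constants, s
#'   (defaults 0.1 and 1.5; decay must exceed rise).
#' @param coupling_beta transient amplitude (dF/F) per second of bout
#'   duration (default 0.02).
#' @param amp_base,amp_sd baseline and SD of the amplitude noise (dF/F).
#' @param p_trig probability that a bout triggers a transient (default 1:
#'   every bout engages the sensor; lower values model unreliable
#'   coupling).
#' @param spont_rate_hz spontaneous (bout-independent) transient rate
#'   (default 0: the default regime is purely bout-locked).
#' @param spont_amp_mean,spont_amp_sd spontaneous amplitude distribution.
#' @param artifact_gain,artifact_tau depth of the shared fractional
#'   motion artifact (both channels are modulated by `1 + gain * a(t)`
#'   with `a` a unit-SD smoothed noise process) and its AR smoothing
#'   constant (s).
#' @param sign +1 for sensors reporting increases; -1 emulates sensors
#'   whose bout-locked response is a decrease.
#' @param seed RNG seed.
#' @return list of class `photometry_sim_params`.
#' @export
photometry_sim_params <- function(sample_rate = 20, acq_rate = 1000,
                                  noise_sd = 1,
                                  b0_470 = 100, b0_405 = 80,
                                  bleach_tau_470 = 2500, bleach_tau_405 = 3500,
                                  kernel_rise = 0.1, kernel_decay = 1.5,
                                  coupling_beta = 0.02,
                                  amp_base = 0.005, amp_sd = 0.008,
                                  p_trig = 1,
                                  spont_rate_hz = 0,
                                  spont_amp_mean = 0.03, spont_amp_sd = 0.01,
                                  artifact_gain = 0.002, artifact_tau = 0.3,
                                  sign = 1, seed = 1) {
  stopifnot(kernel_decay > kernel_rise, kernel_rise > 0,
            p_trig >= 0, p_trig <= 1, sample_rate > 0)
  structure(as.list(environment()), class = "photometry_sim_params")
}

# unit-peak double-exponential kernel evaluated at times t >= 0
.transient_kernel <- function(t, rise, decay) {
  tp <- log(decay / rise) * rise * decay / (decay - rise)
  peak <- exp(-tp / decay) - exp(-tp / rise)
  (exp(-t / decay) - exp(-t / rise)) / peak
}

#' Simulate a photometry session locked to a bout schedule
#'
#' @param params a [photometry_sim_params()].
#' @param bouts ground-truth bout schedule (data frame with `onset_s`,
#'   `duration_s`) as produced by [simulate_bout_schedule()] or
#'   [simulate_pose_session()]; may have zero rows.
#' @param session_s session length in seconds; defaults to the schedule's
#'   `session_s` attribute.
#' @return list with `recording` (a [photometry_recording()]) and `truth`
#'   (list: `transients` data frame with `time_s`, `amplitude`, `source`,
#'   `bout_duration_s`; `components` with the clean bleach/artifact/
#'   indicator parts; `params`).
#' @export
simulate_photometry_session <- function(params, bouts,
                                        session_s = attr(bouts, "session_s")) {
  stopifnot(inherits(params, "photometry_sim_params"))
  p <- params
  if (is.null(session_s)) stopf("session_s unknown")
  fs <- p$sample_rate
  n <- round(session_s * fs)
  t <- (seq_len(n) - 1L) / fs
  with_seed(p$seed + 2L, {
    # event times and amplitudes
    ev_t <- numeric(0); ev_a <- numeric(0); ev_src <- character(0)
    ev_d <- numeric(0)
    if (nrow(bouts)) {
      trig <- stats::rbinom(nrow(bouts), 1L, p$p_trig) == 1L
      if (any(trig)) {
        d <- bouts$duration_s[trig]
        a <- pmax(0, p$amp_base + p$coupling_beta * d +
                    stats::rnorm(sum(trig), 0, p$amp_sd))
        ev_t <- c(ev_t, bouts$onset_s[trig])
        ev_a <- c(ev_a, a)
        ev_src <- c(ev_src, rep("triggered", sum(trig)))
        ev_d <- c(ev_d, d)
      }
    }
    nsp <- stats::rpois(1L, p$spont_rate_hz * session_s)
    if (nsp > 0L) {
      ev_t <- c(ev_t, sort(stats::runif(nsp, 0, session_s - 2)))
      ev_a <- c(ev_a, pmax(0, stats::rnorm(nsp, p$spont_amp_mean, p$spont_amp_sd)))
      ev_src <- c(ev_src, rep("spontaneous", nsp))
      ev_d <- c(ev_d, rep(NA_real_, nsp))
    }
    # indicator trace as a sum of kernels
    C <- numeric(n)
    span <- ceiling(8 * p$kernel_decay * fs)
    for (j in seq_along(ev_t)) {
      i0 <- floor(ev_t[j] * fs) + 1L
      if (i0 > n) next
      ii <- i0:min(n, i0 + span)
      C[ii] <- C[ii] + ev_a[j] * .transient_kernel(t[ii] - ev_t[j],
                                                   p$kernel_rise, p$kernel_decay)
    }
    bleach470 <- p$b0_470 * exp(-t / p$bleach_tau_470)
    bleach405 <- p$b0_405 * exp(-t / p$bleach_tau_405)
    phi <- exp(-1 / (fs * p$artifact_tau))
    innov <- stats::rnorm(n)
    artifact <- as.numeric(stats::filter(innov, phi, method = "recursive"))
    artifact <- artifact / stats::sd(artifact)
    noise_eff <- p$noise_sd * sqrt(p$sample_rate / p$acq_rate)
    # motion artifact modulates each channel in proportion to its own
    # brightness (shared fractional modulation of depth artifact_gain)
    am <- 1 + p$artifact_gain * artifact
    sig470 <- bleach470 * (1 + p$sign * C) * am + stats::rnorm(n, 0, noise_eff)
    sig405 <- bleach405 * am + stats::rnorm(n, 0, noise_eff)
    rec <- photometry_recording(t, sig470, sig405)
    truth <- list(
      transients = data.frame(time_s = ev_t, amplitude = ev_a,
                              source = ev_src, bout_duration_s = ev_d,
                              stringsAsFactors = FALSE),
      components = list(bleach_470 = bleach470, bleach_405 = bleach405,
                        artifact = artifact, indicator = C),
      params = params
    )
    list(recording = rec, truth = truth)
  })
}

#' Multi-day study design
#'
#' Emulates a multi-day repeated-restraint design: daily sessions per
#' subject, with the bout-signal coupling decaying geometrically across
#' days (habituation to the repeated, homotypic stressor:
#' `beta_day = coupling_beta * habituation_delta^(day-1)`) and an optional
#' drug day on which the bout rate and spontaneous transient rate are
#' multiplied (emulating an anxiogenic challenge).
#'
#' @param n_subjects number of subjects (default 6).
#' @param days number of daily sessions (default 6).
#' @param habituation_delta per-day coupling multiplier (default 1: no
#'   habituation).
#' @param drug_day day index receiving the rate multipliers, or `NA`
#'   (default 5).
#' @param drug_bout_rate_mult,drug_spont_mult multipliers applied on the
#'   drug day (defaults 1.5).
#' @param sign sensor sign passed to the photometry generator.
#' @param behavior,photometry parameter templates; per-subject-day seeds
#'   are derived from `seed`.
#' @param seed base seed.
#' @return list of class `study_design`.
#' @export
study_design <- function(n_subjects = 6, days = 6, habituation_delta = 1,
                         drug_day = 5, drug_bout_rate_mult = 1.5,
                         drug_spont_mult = 1.5, sign = 1,
                         behavior = behavior_sim_params(),
                         photometry = photometry_sim_params(),
                         seed = 1) {
  stopifnot(n_subjects >= 1, days >= 1, habituation_delta >= 0)
  structure(as.list(environment()), class = "study_design")
}

#' Simulate a full multi-day study
#'
#' Applies the design's per-day coupling and rate multipliers and derives
#' a deterministic seed for every subject-day cell, so the whole study is
#' a pure function of (design, seed).
#'
#' @param design a [study_design()].
#' @return nested list `res[[subject]][[day]]` with elements `pose`
#'   (track + truth), `photometry` (recording + truth), and `day_params`.
#' @export
simulate_study <- function(design) {
  stopifnot(inherits(design, "study_design"))
  d <- design
  res <- list()
  for (s in seq_len(d$n_subjects)) {
    subj <- list()
    for (day in seq_len(d$days)) {
      cell_seed <- (d$seed %% 1000000L) * 1000L + s * 100L + day
      bp <- d$behavior
      pp <- d$photometry
      bp$seed <- cell_seed
      pp$seed <- cell_seed
      pp$coupling_beta <- pp$coupling_beta * d$habituation_delta^(day - 1)
      pp$sign <- d$sign
      if (!is.na(d$drug_day) && day == d$drug_day) {
        bp$bout_rate_per_min <- bp$bout_rate_per_min * d$drug_bout_rate_mult
        pp$spont_rate_hz <- pp$spont_rate_hz * d$drug_spont_mult
      }
      pose <- simulate_pose_session(bp)
      phot <- simulate_photometry_session(pp, pose$truth$bouts)
      subj[[as.character(day)]] <- list(pose = pose, photometry = phot,
                                        day_params = list(behavior = bp,
                                                          photometry = pp))
    }
    res[[sprintf("subject_%02d", s)]] <- subj
  }
  res
}

#' Write a simulated session to the on-disk text formats
#'
#' Writes the pose track in the flat dialect, the photometry recording as
#' `time_s, ch470, ch405`, and the ground truth as a JSON-like YAML
#' sidecar, so the readers can be exercised on generator output.
#'
#' @param sim output of [simulate_pose_session()].
#' @param phot output of [simulate_photometry_session()] (optional).
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_simulated_session <- function(sim, phot = NULL, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  nf <- n_frames(sim$track)
  flat <- do.call(rbind, lapply(names(sim$track$positions), function(nm) {
    m <- sim$track$positions[[nm]]
    data.frame(frame = seq_len(nf) - 1L, point = nm, x = m[, 1L], y = m[, 2L])
  }))
  p1 <- file.path(dir, "pose.csv")
  utils::write.csv(flat, p1, row.names = FALSE)
  paths <- c(paths, p1)
  if (!is.null(phot)) {
    rec <- phot$recording
    p2 <- file.path(dir, "photometry.csv")
    utils::write.csv(data.frame(time_s = rec$time, ch470 = rec$signal,
                                ch405 = rec$reference), p2, row.names = FALSE)
    paths <- c(paths, p2)
  }
  p3 <- file.path(dir, "ground_truth.yaml")
  yaml::write_yaml(list(bouts = sim$truth$bouts,
                        n_bouts = nrow(sim$truth$bouts)), p3)
  paths <- c(paths, p3)
  invisible(paths)
}
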