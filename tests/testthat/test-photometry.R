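test_that("photometry tables read back and reject broken time bases", {
  f <- withr::local_tempfile(fileext = ".csv")
  t <- (0:999) / 20
  write.csv(data.frame(time_s = t, ch470 = 100 + rnorm(1000),
                       ch405 = 80 + rnorm(1000)), f, row.names = FALSE)
  rec <- read_photometry_table(f)
  expect_equal(rec$sample_rate, 20, tolerance = 1e-6)
  expect_equal(diff(range(rec$time)), 49.95, tolerance = 1e-9)

  t2 <- t; t2[500] <- t2[499]  # repeated timestamp
  f2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(time_s = t2, ch470 = rnorm(1000)), f2, row.names = FALSE)
  expect_error(read_photometry_table(f2),
               class = "strugglescope_format_error")
})

test_that("decimation block-averages and preserves the mean", {
  set.seed(2)
  n <- 50000  # 50 s at 1 kHz
  t <- (seq_len(n) - 1) / 1000
  y <- 100 + 5 * sin(2 * pi * 0.2 * t) + rnorm(n)
  rec <- photometry_recording(t, y)
  dec <- decimate_recording(rec, 20)
  expect_equal(length(dec$time), n / 50)
  expect_lt(abs(mean(dec$signal) - mean(y)) / mean(y), 0.001)
  # block-average oracle on the first blocks
  expect_equal(dec$signal[1], mean(y[1:50]), tolerance = 1e-12)
  expect_equal(dec$signal[7], mean(y[301:350]), tolerance = 1e-12)
})

test_that("isosbestic regression recovers exact and noisy linear relations", {
  t <- (0:499) / 20
  ref <- 80 + sin(t)
  rec1 <- photometry_recording(t, ref, ref)
  f1 <- fit_isosbestic(rec1)
  expect_equal(f1$slope, 1, tolerance = 1e-9)
  expect_equal(f1$intercept, 0, tolerance = 1e-7)

  rec2 <- photometry_recording(t, 2 * ref + 3, ref)
  f2 <- fit_isosbestic(rec2)
  expect_equal(f2$slope, 2, tolerance = 1e-9)
  expect_equal(f2$intercept, 3, tolerance = 1e-7)

  set.seed(4)
  sig <- 1.7 * ref - 12 + rnorm(500)
  f3 <- fit_isosbestic(photometry_recording(t, sig, ref))
  # closed-form normal-equations oracle
  slope_o <- cov(ref, sig) / var(ref)
  expect_equal(f3$slope, slope_o, tolerance = 1e-9)
  expect_equal(f3$intercept, mean(sig) - slope_o * mean(ref), tolerance = 1e-9)

  expect_error(fit_isosbestic(photometry_recording(t, sig, rep(80, 500))),
               class = "strugglescope_degenerate_fit")
})

test_that("dF/F is the fractional difference from the fitted reference", {
  t <- (0:99) / 20
  ref <- 80 + cos(t)
  rec <- photometry_recording(t, ref, ref)
  fit <- fit_isosbestic(rec)
  expect_equal(compute_dff(rec, fit)$dff, rep(0, 100), tolerance = 1e-12)

  rec2 <- photometry_recording(t, 1.1 * ref, ref)
  fit2 <- list(slope = 1, intercept = 0, fitted_reference = ref)
  class(fit2) <- "isosbestic_fit"
  expect_equal(compute_dff(rec2, fit2)$dff, rep(0.1, 100), tolerance = 1e-12)

  # element-wise spreadsheet-style oracle
  set.seed(8)
  sig <- 90 + rnorm(100)
  f0 <- 85 + runif(100)
  fit3 <- structure(list(slope = NA, intercept = NA, fitted_reference = f0),
                    class = "isosbestic_fit")
  expect_equal(compute_dff(photometry_recording(t, sig, f0), fit3)$dff,
               (sig - f0) / f0, tolerance = 1e-12)

  fit4 <- structure(list(fitted_reference = c(f0[-100], -1)),
                    class = "isosbestic_fit")
  expect_error(compute_dff(photometry_recording(t, sig, f0), fit4),
               class = "strugglescope_domain_error")
})

test_that("airPLS reproduces flat baselines and is shift-equivariant", {
  expect_equal(airpls_baseline(rep(2.5, 500)), rep(2.5, 500), tolerance = 1e-6)
  # shift equivariance: the weighted smoother is linear for a fixed weight
  # path, so with the stopping rule disabled (conv ~ 0) both runs take the
  # same path and baselines differ by exactly the shift
  set.seed(5)
  y <- rnorm(800) + 10 * exp(-(1:800 - 400)^2 / 200)
  b1 <- airpls_baseline(y, conv = 1e-12)
  b2 <- airpls_baseline(y + 7.3, conv = 1e-12)
  expect_equal(b2, b1 + 7.3, tolerance = 1e-6)
})

test_that("airPLS tracks bleaching drift at session scale within 1%", {
  t <- seq(0, 1799.95, by = 0.05)
  drift <- 100 * exp(-t / 2500)
  b <- airpls_baseline(drift)
  expect_lt(max(abs(b - drift)) / diff(range(drift)), 0.01)
})

test_that("airPLS excludes a positive peak from the baseline", {
  # flat baseline + large bump: the estimated baseline must ignore the
  # peak entirely and stay on the flat level everywhere
  n <- 2000
  bump <- 400:600
  y <- rep(0.5, n)
  y[bump] <- y[bump] + 10 * exp(-(bump - 500)^2 / 2000)
  b <- airpls_baseline(y)
  expect_lt(max(abs(b[bump] - 0.5)), 0.05)
  expect_lt(max(abs(b[-bump] - 0.5)), 0.01)
})

test_that("session standardization has mean 0, sd 1, and affine invariance", {
  set.seed(6)
  x <- rnorm(300)
  z <- standardize_trace(x)
  expect_equal(mean(z), 0, tolerance = 1e-9)
  expect_equal(sd(z), 1, tolerance = 1e-9)
  expect_equal(standardize_trace(3 * x + 11), z, tolerance = 1e-9)

  y <- c(0, 0, 0, 10)  # hand calc: mean 2.5, sd 5
  expect_equal(standardize_trace(y), c(-0.5, -0.5, -0.5, 1.5), tolerance = 1e-12)
  expect_error(standardize_trace(rep(1, 50)),
               class = "strugglescope_degenerate_input")
})

test_that("transients are maximal runs at or above threshold", {
  expect_equal(nrow(detect_transients(rnorm(100), fs = 1)), 0L)
  tr <- detect_transients(c(0, 3, 3, 0, 5, 0), fs = 1)
  expect_equal(nrow(tr), 2L)
  expect_equal(tr$max_peak_z, c(3, 5))
  expect_equal(tr$start_s, c(1, 4))
  expect_equal(tr$end_s, c(2, 4))
  expect_equal(tr$area, c(3, 0))  # trapezoid; single-sample run has area 0
})

test_that("detection equals the brute-force scanner on random traces", {
  set.seed(10)
  for (i in 1:100) {
    n <- sample(20:400, 1)
    z <- rnorm(n, sd = 2)
    fs <- sample(c(1, 10, 20), 1)
    thr <- runif(1, 0.5, 3.5)
    ms <- sample(1:3, 1)
    got <- detect_transients(z, fs = fs, z_threshold = thr, min_samples = ms)
    want <- oracle_scan_transients(z, (seq_len(n) - 1) / fs, thr, ms)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want)) {
      expect_equal(got$start_s, want$start_s, tolerance = 1e-9)
      expect_equal(got$end_s, want$end_s, tolerance = 1e-9)
      expect_equal(got$max_peak_z, want$max_peak_z, tolerance = 1e-9)
      expect_equal(got$area, want$area, tolerance = 1e-9)
    }
  }
})

test_that("transient frequency is count per second", {
  empty <- detect_transients(rep(0, 60), fs = 1)
  expect_equal(transient_frequency(empty, 60), 0)
  tr <- detect_transients(rep(c(5, 0, 0, 0, 0, 0, 0, 0, 0, 0), 6), fs = 1)
  expect_equal(transient_frequency(tr, 60), 0.1)
})

test_that("well-separated high-SNR injected transients give exact frequency", {
  set.seed(12)
  fs <- 20; dur <- 600
  tt <- (seq_len(dur * fs) - 1) / fs
  times <- seq(10, 590, by = 20)[1:30]
  y <- rnorm(length(tt), 0, 0.01)
  for (t0 in times) {
    ii <- which(tt >= t0 & tt <= t0 + 12)
    y[ii] <- y[ii] + oracle_kernel(tt[ii] - t0)
  }
  z <- standardize_trace(y)
  tr <- detect_transients(z, time = tt)
  expect_equal(nrow(tr), 30L)
  expect_equal(transient_frequency(tr, dur), 0.05)
})
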