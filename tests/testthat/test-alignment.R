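test_that("peri-event configuration is validated", {
  expect_error(peri_event_config(baseline = c(-5, 1)))
  expect_error(peri_event_config(window = c(-2, 5), baseline = c(-5, -3)))
  expect_error(peri_event_config(windows = list(post = c(0, 20))))
  cfg <- peri_event_config()
  expect_equal(cfg$window, c(-5, 10))
  expect_equal(cfg$baseline, c(-5, -3))
  expect_equal(cfg$windows$post, c(0, 5))
  expect_equal(cfg$offset_s, 0)
})

test_that("rows are extracted around onsets and edge bouts are flagged", {
  fs <- 20
  vals <- sin((0:(600 * fs - 1)) / 100)
  trace <- make_trace(vals, fs = fs)
  bouts <- make_bouts(c(100, 2), session_s = 600)
  al <- align_to_events(trace, bouts)
  expect_false(al$events$excluded[1])
  expect_true(al$events$excluded[2])
  expect_equal(al$events$reason[2], "window_out_of_range")
  # the retained row spans trace samples for t = 95..110 s
  idx <- round((100 + al$time) * fs) + 1
  raw <- vals[idx]
  bsel <- al$time >= -5 - 1e-9 & al$time <= -3 + 1e-9
  expect_equal(al$z[1, ],
               (raw - mean(raw[bsel])) / sd(raw[bsel]), tolerance = 1e-12)
})

test_that("peri-event Z uses the baseline window mean and sd", {
  grid <- seq(-5, 10, by = 1)
  cfg <- peri_event_config(window = c(-5, 10), baseline = c(-5, -4),
                           windows = list(post = c(0, 5)))
  # baseline samples {0, 2}: mean 1, sd sqrt(2)
  row <- rep(1, length(grid))
  row[1:2] <- c(0, 2)
  row[grid == 1] <- 3
  z <- zscore_peri_event(row, grid, cfg)
  expect_equal(z[grid == 1], (3 - 1) / sqrt(2), tolerance = 1e-12)
  # shift invariance
  expect_equal(zscore_peri_event(row + 100, grid, cfg), z, tolerance = 1e-9)
  # zero-variance baseline is degenerate
  expect_null(zscore_peri_event(rep(1, length(grid)), grid, cfg))
})

test_that("retained rows have baseline mean 0 and sd 1 by construction", {
  set.seed(21)
  fs <- 20
  trace <- make_trace(rnorm(600 * fs), fs = fs)
  bouts <- make_bouts(seq(20, 560, by = 30))
  al <- align_to_events(trace, bouts)
  bsel <- al$time >= -5 - 1e-9 & al$time <= -3 + 1e-9
  for (i in which(!al$events$excluded)) {
    expect_equal(mean(al$z[i, bsel]), 0, tolerance = 1e-9)
    expect_equal(sd(al$z[i, bsel]), 1, tolerance = 1e-9)
  }
})

test_that("AUC is a signed trapezoidal integral over the window", {
  grid <- seq(-5, 10, by = 0.05)
  expect_equal(compute_auc(rep(0, length(grid)), grid, c(0, 5)), 0)
  expect_equal(compute_auc(rep(1, length(grid)), grid, c(0, 5)), 5,
               tolerance = 1e-9)
  tri <- ifelse(grid >= 0 & grid <= 5, grid * 2 / 5, 0)
  expect_equal(compute_auc(tri, grid, c(0, 5)), 5, tolerance = 1e-9)
  # negative deflections give negative area
  expect_equal(compute_auc(-tri, grid, c(0, 5)), -5, tolerance = 1e-9)
})

test_that("AUC is additive over adjacent windows", {
  set.seed(22)
  grid <- seq(-5, 10, by = 0.05)
  for (i in 1:20) {
    z <- rnorm(length(grid))
    expect_equal(compute_auc(z, grid, c(0, 5)),
                 compute_auc(z, grid, c(0, 2)) + compute_auc(z, grid, c(2, 5)),
                 tolerance = 1e-9)
  }
})

test_that("max peak is the signed window maximum", {
  grid <- 0:2
  expect_equal(compute_max_peak(c(0, 0, 0), grid, c(0, 2)), 0)
  expect_equal(compute_max_peak(c(-1, 4, 2), grid, c(0, 2)), 4)
  expect_equal(compute_max_peak(c(-3, -1, -2), grid, c(0, 2)), -1)
  set.seed(23)
  g2 <- seq(-5, 10, by = 0.05)
  for (i in 1:20) {
    z <- rnorm(length(g2))
    sel <- g2 >= 0 & g2 <= 5
    expect_equal(compute_max_peak(z, g2, c(0, 5)), max(z[sel]))
  }
})

test_that("bout metrics carry per-window AUC/peak and positivity flags", {
  fs <- 20
  trace <- make_trace(rnorm(600 * fs, sd = 0.1), fs = fs)
  bouts <- make_bouts(c(100, 200, 300))
  m <- bout_metrics(align_to_events(trace, bouts))
  expect_true(all(c("auc_post", "peak_post", "auc_pre", "peak_pre",
                    "auc_positive", "peak_positive") %in% names(m)))
  expect_equal(m$auc_positive, m$auc_post > 0)
})

test_that("heatmap companion trace is the per-timepoint mean with sem", {
  al <- structure(list(
    z = rbind(c(0, 2), c(2, 0)), time = c(0, 1),
    events = data.frame(bout = 1:2, onset_s = c(1, 2), duration_s = 1,
                        type = "full_body", excluded = FALSE, reason = NA),
    cfg = peri_event_config(), sample_rate = 1), class = "event_aligned_matrix")
  hm <- build_heatmap(al)
  expect_equal(hm$mean_trace$mean, c(1, 1))
  expect_equal(hm$mean_trace$sem, c(1, 1))

  one <- al; one$z <- one$z[1, , drop = FALSE]; one$events <- one$events[1, ]
  hm1 <- build_heatmap(one)
  expect_equal(hm1$mean_trace$mean, c(0, 2))
  expect_equal(hm1$mean_trace$sem, c(0, 0))
})

test_that("display clipping never touches the stored metrics", {
  al <- structure(list(
    z = rbind(c(0, 7), c(1, -6)), time = c(0, 1),
    events = data.frame(bout = 1:2, onset_s = c(1, 2), duration_s = 1,
                        type = "full_body", excluded = FALSE, reason = NA),
    cfg = peri_event_config(windows = list(post = c(0, 1))),
    sample_rate = 1), class = "event_aligned_matrix")
  hm <- build_heatmap(al, clip = c(-3, 3))
  expect_equal(range(hm$plot$data$z), c(-3, 3))
  expect_equal(compute_max_peak(al$z[1, ], al$time, c(0, 1)), 7)
})

test_that("the +10 s offset control destroys bout-locked signal", {
  sim <- simulate_pose_session(behavior_sim_params(seed = 6))
  phot <- simulate_photometry_session(photometry_sim_params(seed = 6),
                                      sim$truth$bouts)
  proc <- process_photometry(phot$recording)
  bt <- segment_bouts(classify_mobility(compute_speeds(sim$track)))
  m0 <- bout_metrics(align_to_events(proc$z, bt, peri_event_config()))
  m10 <- bout_metrics(align_to_events(proc$z, bt,
                                      peri_event_config(offset_s = 10)))
  a0 <- mean(m0$auc_post[!m0$excluded])
  a10 <- mean(m10$auc_post[!m10$excluded])
  expect_gte(1 - a10 / a0, 0.7)
})

test_that("aligned matrices round-trip through the text export", {
  fs <- 20
  trace <- make_trace(rnorm(200 * fs), fs = fs)
  al <- align_to_events(trace, make_bouts(c(50, 100), session_s = 200))
  f <- withr::local_tempfile(fileext = ".csv")
  write_aligned_matrix(al, f)
  back <- read.csv(f, check.names = FALSE)
  expect_equal(nrow(back), 2L)
  expect_equal(as.numeric(back[1, -(1:5)]), unname(al$z[1, ]),
               tolerance = 1e-6)
})
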