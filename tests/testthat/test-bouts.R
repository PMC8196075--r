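test_that("all-immobile sessions yield an empty bout table", {
  bt <- segment_bouts(mob_from_frames(200))
  expect_s3_class(bt, "bout_table")
  expect_equal(nrow(bt), 0L)
  expect_equal(attr(bt, "session_s"), 20)
})

test_that("mobile runs separated by gaps <= 0.7 s merge into one bout", {
  # frames here are 1-based; spec's frame indices are 0-based
  mob <- mob_from_frames(60, head_frames = c(11:15, 21:23))  # 0.5 s gap
  bt <- segment_bouts(mob)
  expect_equal(nrow(bt), 1L)
  expect_equal(bt$onset_s, 1.0)
  expect_equal(bt$offset_s, 2.2)
  expect_equal(bt$duration_s, 1.3)
})

test_that("an all-immobile run > 0.7 s terminates the bout", {
  mob <- mob_from_frames(120, head_frames = c(11:15, 24:26))  # 0.8 s gap
  bt <- segment_bouts(mob)
  expect_equal(nrow(bt), 2L)
  expect_equal(bt$onset_s, c(1.0, 2.3))
})

test_that("a sub-frame gap parameter is a config error", {
  expect_error(segment_bouts(mob_from_frames(50), gap_s = 0.05),
               class = "strugglescope_config_error")
})

test_that("bout types reflect which points moved anywhere inside the bout", {
  expect_equal(classify_bout_type(TRUE, FALSE), "head_only")
  expect_equal(classify_bout_type(FALSE, TRUE), "tail_only")
  expect_error(classify_bout_type(FALSE, FALSE))
  # head on frames 11-13, tail on frame 15 only: same bout, full body
  mob <- mob_from_frames(60, head_frames = 11:13, tail_frames = 15)
  bt <- segment_bouts(mob)
  expect_equal(nrow(bt), 1L)
  expect_equal(bt$type, "full_body")
})

test_that("bout summaries tally counts, times and trial percentages", {
  s <- summarize_bouts(segment_bouts(mob_from_frames(18000)))
  expect_equal(sum(s$by_type$count), 0L)
  expect_equal(s$pct_immobile, 100)

  # two full-body bouts of 2 s and 4 s in a 60 s session
  mob <- mob_from_frames(600, head_frames = c(101:120, 301:340),
                         tail_frames = c(101:120, 301:340))
  s2 <- summarize_bouts(segment_bouts(mob))
  fb <- s2$by_type[s2$by_type$type == "full_body", ]
  expect_equal(fb$count, 2L)
  expect_equal(fb$total_s, 6)
  expect_equal(fb$mean_s, 3)
  expect_equal(fb$pct_of_trial, 10)
  expect_equal(s2$pct_immobile, 90)
})

test_that("multi-type sessions match an independent hand tally", {
  mob <- mob_from_frames(1200,
                         head_frames = c(51:60, 201:215, 501:520),
                         tail_frames = c(201:210, 801:804))
  bt <- segment_bouts(mob)
  # hand tally: bouts at frames 51-60 (head), 201-215 (full), 501-520
  # (head), 801-804 (tail); durations 1.0, 1.5, 2.0, 0.4 s
  expect_equal(bt$type, c("head_only", "full_body", "head_only", "tail_only"))
  s <- summarize_bouts(bt)
  # table rows are ordered head_only, tail_only, full_body
  expect_equal(s$by_type$count, c(2L, 1L, 1L))
  expect_equal(s$by_type$total_s, c(3.0, 0.4, 1.5))
  expect_equal(s$by_type$mean_s, c(1.5, 0.4, 1.5))
})

test_that("per-day full-body counts assemble into a long table", {
  b1 <- segment_bouts(mob_from_frames(600, head_frames = 101:120,
                                      tail_frames = 101:120))
  b0 <- segment_bouts(mob_from_frames(600))
  tab <- count_bouts_by_day(list(m1 = list(`1` = b1, `2` = b0)))
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$n_full_body, c(1L, 0L))
})

test_that("segmentation is order-independent across a long immobile span", {
  set.seed(3)
  m1 <- matrix(runif(400) < 0.2, 200, 2,
               dimnames = list(NULL, c("head_fiber", "tail_tip")))
  m2 <- matrix(runif(400) < 0.2, 200, 2,
               dimnames = list(NULL, c("head_fiber", "tail_tip")))
  pad <- matrix(FALSE, 50, 2, dimnames = list(NULL, c("head_fiber", "tail_tip")))
  joint <- segment_bouts(make_mobility(rbind(m1, pad, m2)))
  a <- segment_bouts(make_mobility(rbind(m1, pad)))
  b <- segment_bouts(make_mobility(rbind(pad, m2)))
  expect_equal(nrow(joint), nrow(a) + nrow(b))
  expect_equal(joint$duration_s, c(a$duration_s, b$duration_s))
})

test_that("no output bouts are separated by immobile runs <= gap_s, and every
           mobile frame falls in exactly one bout", {
  set.seed(9)
  for (rep in 1:20) {
    m <- matrix(runif(600) < runif(1, 0.05, 0.4), 300, 2,
                dimnames = list(NULL, c("head_fiber", "tail_tip")))
    bt <- segment_bouts(make_mobility(m))
    if (nrow(bt) > 1L)
      expect_true(all(bt$onset_s[-1] - bt$offset_s[-nrow(bt)] > 0.7 + 1/10 - 1e-9))
    mobile_frames <- which(rowSums(m) > 0) - 1L
    covered <- unlist(lapply(seq_len(nrow(bt)), function(i)
      seq(round(bt$onset_s[i] * 10), round(bt$offset_s[i] * 10))))
    expect_true(all(mobile_frames %in% covered))
    expect_equal(anyDuplicated(covered), 0L)
  }
})

test_that("true bouts are recovered from a simulated session", {
  sim <- simulate_pose_session(behavior_sim_params(seed = 4))
  bt <- segment_bouts(classify_mobility(compute_speeds(sim$track)))
  m <- match_bouts(bt, sim$truth$bouts)
  expect_gte(m$recall, 0.9)
  expect_lte(m$fdp, 0.1)
  expect_gte(m$type_accuracy, 0.9)
})

test_that("bout tables export to csv and BED-like intervals", {
  mob <- mob_from_frames(600, head_frames = 101:120, tail_frames = 101:120)
  bt <- segment_bouts(mob, session_id = "s1")
  f1 <- withr::local_tempfile(fileext = ".csv")
  write_bout_table(bt, f1)
  back <- read.csv(f1)
  expect_equal(back$onset_s, 10)
  expect_equal(back$type, "full_body")
  f2 <- withr::local_tempfile(fileext = ".bed")
  write_bout_table(bt, f2, format = "bed")
  bed <- read.table(f2, sep = "\t")
  expect_equal(bed$V2, 10000L)  # 0-based start, ms
  expect_equal(bed$V3 - bed$V2, 2000L)
})
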