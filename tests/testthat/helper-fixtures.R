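# fixture builders shared across test files

# write a DLC-style three-row-header pose CSV; pts is a named list of
# n x 2 matrices, conf an optional named list of confidence vectors
write_dlc_fixture <- function(path, pts, conf = NULL) {
  nms <- names(pts)
  n <- nrow(pts[[1]])
  has_conf <- !is.null(conf)
  per <- if (has_conf) 3 else 2
  hdr1 <- c("scorer", rep("model", length(nms) * per))
  hdr2 <- c("bodyparts", rep(nms, each = per))
  hdr3 <- c("coords", rep(if (has_conf) c("x", "y", "likelihood") else c("x", "y"),
                          length(nms)))
  rows <- sapply(seq_len(n), function(i) {
    vals <- unlist(lapply(nms, function(nm) {
      v <- c(pts[[nm]][i, 1], pts[[nm]][i, 2])
      if (has_conf) v <- c(v, conf[[nm]][i])
      v
    }))
    paste(c(i - 1, vals), collapse = ",")
  })
  writeLines(c(paste(hdr1, collapse = ","), paste(hdr2, collapse = ","),
               paste(hdr3, collapse = ","), rows), path)
  path
}

# mobility_series built directly from a logical matrix (bypasses thresholds)
make_mobility <- function(mobile, fps = 10) {
  structure(list(mobile = mobile,
                 thresholds = stats::setNames(rep(0, ncol(mobile)),
                                              colnames(mobile)),
                 fps = fps, config = NULL),
            class = "mobility_series")
}

# mobility matrix with given mobile frame sets (1-based) for head/tail
mob_from_frames <- function(n, head_frames = integer(), tail_frames = integer(),
                            fps = 10) {
  m <- matrix(FALSE, n, 2, dimnames = list(NULL, c("head_fiber", "tail_tip")))
  m[head_frames, "head_fiber"] <- TRUE
  m[tail_frames, "tail_tip"] <- TRUE
  make_mobility(m, fps)
}

# quick session trace data frame
make_trace <- function(values, fs = 20, t0 = 0) {
  data.frame(time = t0 + (seq_along(values) - 1) / fs, value = values)
}

# minimal bout table for alignment tests
make_bouts <- function(onsets, durations = rep(1, length(onsets)),
                       types = rep("full_body", length(onsets)),
                       session_s = max(onsets) + 60, fps = 10) {
  df <- data.frame(bout = seq_along(onsets), onset_s = onsets,
                   offset_s = onsets + durations - 1 / fps,
                   duration_s = durations, type = types,
                   mobile_frames_head = 1L, mobile_frames_tail = 1L,
                   truncated = FALSE, stringsAsFactors = FALSE)
  structure(df, class = c("bout_table", "data.frame"),
            session_s = session_s, fps = fps, gap_s = 0.7,
            session_id = "fixture")
}
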