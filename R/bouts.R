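#' Segment mobility state into struggle bouts
#'
#' A bout opens at any frame where a tracked point goes from immobile to
#' mobile while no bout is open (a mobile first frame also opens a bout);
#' that frame is time 0.0 of the bout. The bout continues until every
#' tracked point has been immobile for strictly longer than `gap_s`
#' seconds (at 10 fps and the default 0.7 s gap, a run of at least 8
#' all-immobile frames), or until the session ends. The bout's offset is
#' the last frame on which any point was mobile before closure, so
#' candidate bouts separated by all-immobile runs of at most `gap_s` are
#' merged into one. Bouts cut off by the end of the session (no confirmed
#' closing gap) are kept and flagged `truncated`.
#'
#' Each bout is typed by which points moved within it: movements of the
#' head only, of the tail only, or of both head and tail anywhere inside
#' the bout ("full body").
#'
#' @param mob a `mobility_series` from [classify_mobility()].
#' @param gap_s all-immobile run (seconds) that terminates a bout; a run
#'   must be strictly longer than this to close a bout. Default 0.7.
#' @param head_point,tail_point column names in `mob$mobile` used for
#'   typing. Points other than these two do not affect the type label but
#'   do keep a bout open.
#' @param session_id label stored with the table.
#' @return a `bout_table`: data frame with columns `bout`, `onset_s`,
#'   `offset_s`, `duration_s`, `type`, `mobile_frames_head`,
#'   `mobile_frames_tail`, `truncated`; attributes `session_s`, `gap_s`,
#'   `fps`, `session_id`.
#' @export
segment_bouts <- function(mob, gap_s = 0.7, head_point = "head_fiber",
                          tail_point = "tail_tip", session_id = "session") {
  stopifnot(inherits(mob, "mobility_series"))
  fps <- mob$fps
  if (gap_s < 1 / fps)
    stopf("gap_s (%g s) is below one frame at %g fps", gap_s, fps,
          class = "strugglescope_config_error")
  m <- mob$mobile
  nf <- nrow(m)
  any_mob <- rowSums(m) > 0
  # split on all-immobile runs strictly longer than gap_s
  max_merge_frames <- floor(gap_s * fps + 1e-9)
  r <- rle(any_mob)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts, end = ends, mobile = r$values)
  mruns <- runs[runs$mobile, , drop = FALSE]
  if (nrow(mruns) == 0L) {
    return(.bout_table(data.frame(), nf, fps, gap_s, session_id))
  }
  # merge mobile runs separated by short immobile gaps
  onset <- mruns$start[1L]
  offset <- mruns$end[1L]
  bouts <- list()
  if (nrow(mruns) > 1L) {
    for (i in 2L:nrow(mruns)) {
      gap_frames <- mruns$start[i] - offset - 1L
      if (gap_frames <= max_merge_frames) {
        offset <- mruns$end[i]
      } else {
        bouts[[length(bouts) + 1L]] <- c(onset, offset)
        onset <- mruns$start[i]
        offset <- mruns$end[i]
      }
    }
  }
  bouts[[length(bouts) + 1L]] <- c(onset, offset)
  bmat <- do.call(rbind, bouts)
  onset_f <- bmat[, 1L] - 1L   # 0-based frames
  offset_f <- bmat[, 2L] - 1L
  has_head <- head_point %in% colnames(m)
  has_tail <- tail_point %in% colnames(m)
  nh <- nt <- integer(nrow(bmat))
  type <- character(nrow(bmat))
  for (i in seq_len(nrow(bmat))) {
    rows <- bmat[i, 1L]:bmat[i, 2L]
    nh[i] <- if (has_head) sum(m[rows, head_point]) else 0L
    nt[i] <- if (has_tail) sum(m[rows, tail_point]) else 0L
    type[i] <- classify_bout_type(head_mobile = nh[i] > 0L,
                                  tail_mobile = nt[i] > 0L)
  }
  truncated <- (nf - 1L - offset_f) <= max_merge_frames
  df <- data.frame(
    bout = seq_len(nrow(bmat)),
    onset_s = onset_f / fps,
    offset_s = offset_f / fps,
    duration_s = (offset_f - onset_f + 1L) / fps,
    type = type,
    mobile_frames_head = nh,
    mobile_frames_tail = nt,
    truncated = truncated,
    stringsAsFactors = FALSE
  )
  .bout_table(df, nf, fps, gap_s, session_id)
}

.bout_table <- function(df, n_frames, fps, gap_s, session_id) {
  if (nrow(df) == 0L) {
    df <- data.frame(bout = integer(), onset_s = numeric(),
                     offset_s = numeric(), duration_s = numeric(),
                     type = character(), mobile_frames_head = integer(),
                     mobile_frames_tail = integer(), truncated = logical(),
                     stringsAsFactors = FALSE)
  }
  structure(df,
            class = c("bout_table", "data.frame"),
            session_s = n_frames / fps, fps = fps, gap_s = gap_s,
            session_id = session_id)
}

#' Type a bout from which points moved inside it
#'
#' "Full body" requires at least one mobile head frame and at least one
#' mobile tail frame anywhere within the bout's span (the head and tail
#' need not move on the same frame); otherwise the bout is head-only or
#' tail-only.
#'
#' @param head_mobile,tail_mobile logicals (or logical vectors of per-frame
#'   flags inside the bout, reduced with `any()`).
#' @return one of `"head_only"`, `"tail_only"`, `"full_body"`.
#' @export
classify_bout_type <- function(head_mobile, tail_mobile) {
  h <- any(head_mobile)
  t <- any(tail_mobile)
  if (!h && !t)
    stopf("a bout must contain at least one mobile frame")
  if (h && t) "full_body" else if (h) "head_only" else "tail_only"
}

BOUT_TYPES <- c("head_only", "tail_only", "full_body")

#' Per-session bout summary
#'
#' Counts, cumulative time, and mean duration per bout type, plus the
#' percent of the trial spent in each type and the immobile remainder.
#'
#' @param table a `bout_table`.
#' @return list with `by_type` (data frame: type, count, total_s, mean_s,
#'   pct_of_trial) and `pct_immobile`.
#' @export
summarize_bouts <- function(table) {
  stopifnot(inherits(table, "bout_table"))
  session_s <- attr(table, "session_s")
  by_type <- data.frame(type = BOUT_TYPES, count = 0L, total_s = 0,
                        mean_s = NA_real_, pct_of_trial = 0,
                        stringsAsFactors = FALSE)
  for (i in seq_along(BOUT_TYPES)) {
    sel <- table$type == BOUT_TYPES[i]
    by_type$count[i] <- sum(sel)
    by_type$total_s[i] <- sum(table$duration_s[sel])
    by_type$mean_s[i] <- if (any(sel)) mean(table$duration_s[sel]) else NA_real_
    by_type$pct_of_trial[i] <- 100 * by_type$total_s[i] / session_s
  }
  list(by_type = by_type,
       pct_immobile = 100 - sum(by_type$pct_of_trial),
       session_s = session_s)
}

#' Full-body bout counts per subject and day
#'
#' Collects the number of full-body bouts from a nested list of bout
#' tables into a long-format table ready for paired statistics.
#'
#' @param tables nested list: `tables[[subject]][[day]]` is a `bout_table`.
#' @return data frame with columns `subject`, `day`, `n_full_body`.
#' @export
count_bouts_by_day <- function(tables) {
  out <- list()
  for (subj in names(tables)) {
    for (day in names(tables[[subj]])) {
      bt <- tables[[subj]][[day]]
      stopifnot(inherits(bt, "bout_table"))
      out[[length(out) + 1L]] <- data.frame(
        subject = subj, day = as.integer(day),
        n_full_body = sum(bt$type == "full_body"),
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}

#' Match detected bouts against ground truth
#'
#' Greedy one-to-one matching by onset time: each true bout is matched to
#' the closest unmatched detected bout whose onset differs by at most
#' `onset_tol_s`. Used for recovery validation against the synthetic
#' generator's ground truth.
#'
#' @param detected,truth data frames with columns `onset_s` and `type`
#'   (a `bout_table` works for both).
#' @param onset_tol_s maximum absolute onset error for a match (default
#'   0.2 s).
#' @return list with `recall` (matched true / total true), `fdp`
#'   (unmatched detected / total detected), `type_accuracy` (matched pairs
#'   with equal type / matched pairs), and the `matches` index table.
#' @export
match_bouts <- function(detected, truth, onset_tol_s = 0.2) {
  nd <- nrow(detected); nt <- nrow(truth)
  if (nt == 0L)
    return(list(recall = NA_real_, fdp = if (nd > 0) 1 else NA_real_,
                type_accuracy = NA_real_, matches = data.frame()))
  used <- logical(nd)
  m_true <- integer(0); m_det <- integer(0)
  for (i in seq_len(nt)) {
    if (nd == 0L) break
    err <- abs(detected$onset_s - truth$onset_s[i])
    err[used] <- Inf
    j <- which.min(err)
    if (is.finite(err[j]) && err[j] <= onset_tol_s + 1e-9) {
      used[j] <- TRUE
      m_true <- c(m_true, i); m_det <- c(m_det, j)
    }
  }
  matches <- data.frame(true_idx = m_true, detected_idx = m_det)
  type_acc <- if (length(m_true))
    mean(truth$type[m_true] == detected$type[m_det]) else NA_real_
  list(
    recall = length(m_true) / nt,
    fdp = if (nd > 0) (nd - length(m_det)) / nd else NA_real_,
    type_accuracy = type_acc,
    matches = matches
  )
}

#' Export a bout table as delimited text
#'
#' Writes `session, onset_s, offset_s, duration_s, type` rows; with
#' `format = "bed"` writes a BED-like 0-based half-open interval table
#' (columns chrom = session id, start, end in integer milliseconds, name =
#' type) for interval tooling.
#'
#' @param table a `bout_table`.
#' @param path output file.
#' @param format `"csv"` (default) or `"bed"`.
#' @export
write_bout_table <- function(table, path, format = c("csv", "bed")) {
  format <- match.arg(format)
  sid <- attr(table, "session_id") %||% "session"
  if (format == "csv") {
    out <- data.frame(session = sid, onset_s = table$onset_s,
                      offset_s = table$offset_s,
                      duration_s = table$duration_s, type = table$type)
    utils::write.csv(out, path, row.names = FALSE)
  } else {
    fps <- attr(table, "fps")
    out <- data.frame(
      chrom = sid,
      start = as.integer(round(table$onset_s * 1000)),
      end = as.integer(round((table$offset_s + 1 / fps) * 1000)),
      name = table$type
    )
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}
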