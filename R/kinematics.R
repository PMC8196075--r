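#' Construct a pose track
#'
#' A pose track holds per-frame 2-D coordinates for a set of named body
#' points tracked at a fixed frame rate. The two canonical points for
#' restraint-stress scoring are the head-mounted fiber (`"head_fiber"`) and
#' the tip of the tail (`"tail_tip"`), but any set of labeled points is
#' accepted.
#'
#' @param positions named list; one `n x 2` numeric matrix (columns x, y in
#'   pixels) per body point, all with the same number of rows.
#' @param fps frames per second (default 10, the standard acquisition rate
#'   for restraint videos).
#' @param confidence optional named list of per-frame tracking confidences
#'   in `[0, 1]`, same structure as `positions`.
#' @return an object of class `pose_track`.
#' @export
pose_track <- function(positions, fps = 10, confidence = NULL) {
  if (!is.list(positions) || is.null(names(positions)) || any(names(positions) == ""))
    stopf("`positions` must be a named list of n x 2 matrices")
  positions <- lapply(positions, function(m) {
    m <- as.matrix(m)
    if (ncol(m) != 2L) stopf("each position matrix must have 2 columns (x, y)")
    storage.mode(m) <- "double"
    colnames(m) <- c("x", "y")
    m
  })
  nf <- vapply(positions, nrow, integer(1))
  if (length(unique(nf)) != 1L)
    stopf("all points must have the same frame count")
  if (!is.numeric(fps) || length(fps) != 1L || fps <= 0)
    stopf("`fps` must be a positive scalar")
  if (any(vapply(positions, function(m) any(!is.finite(m)), logical(1))))
    stopf("positions contain non-finite coordinates")
  structure(
    list(positions = positions, fps = fps, confidence = confidence),
    class = "pose_track"
  )
}

#' @export
print.pose_track <- function(x, ...) {
  cat(sprintf(
    "<pose_track> %d frames @ %g fps, %d point(s): %s\n",
    n_frames(x), x$fps, length(x$positions),
    paste(names(x$positions), collapse = ", ")
  ))
  invisible(x)
}

n_frames <- function(track) nrow(track$positions[[1L]])

#' Read a pose-estimation table
#'
#' Reads per-frame body-point coordinates from delimited text in either of
#' two dialects: the three-row-header dialect written by DeepLabCut-style
#' markerless trackers (header rows scorer / bodyparts / coords, then one
#' row per frame with x, y and optionally likelihood columns per body
#' part), or a flat dialect with columns `frame, point, x, y[, confidence]`.
#' The dialect is detected automatically.
#'
#' When a likelihood/confidence column is present and `conf_threshold` is
#' set, coordinates whose confidence falls below the threshold are replaced
#' by linear interpolation between the nearest confident frames (endpoints
#' are carried from the nearest confident value). By default no confidence
#' filtering is applied.
#'
#' @param path path to a delimited-text file.
#' @param point_map optional named character vector mapping canonical point
#'   names to the labels used in the file, e.g.
#'   `c(head_fiber = "fiber", tail_tip = "tailTip")`. Points not listed are
#'   read under their file labels.
#' @param fps frames per second recorded with the track (default 10).
#' @param conf_threshold confidence cutoff in `[0, 1]` below which
#'   coordinates are interpolated; `NULL` (default) disables filtering.
#' @param sep field separator (default `","`).
#' @return a [pose_track()].
#' @export
read_pose_table <- function(path, point_map = NULL, fps = 10,
                            conf_threshold = NULL, sep = ",") {
  if (!file.exists(path)) stopf("file not found: %s", path)
  head_lines <- readLines(path, n = 3L)
  fields1 <- strsplit(head_lines[1L], sep, fixed = TRUE)[[1L]]
  is_dlc <- length(head_lines) >= 3L &&
    (tolower(fields1[1L]) %in% c("scorer", "")) &&
    grepl("bodyparts", strsplit(head_lines[2L], sep, fixed = TRUE)[[1L]][1L],
          ignore.case = TRUE)
  raw <- if (is_dlc) {
    .read_pose_dlc(path, sep)
  } else {
    .read_pose_flat(path, sep)
  }
  # raw: list(points = named list of (x, y, conf-or-NULL), frame = index)
  if (is.unsorted(raw$frame, strictly = TRUE))
    stopf("non-monotonic or duplicated frame index", class = "strugglescope_format_error")
  labels <- names(raw$points)
  if (!is.null(point_map)) {
    missing <- setdiff(unname(point_map), labels)
    if (length(missing))
      stopf("point(s) not present in table: %s", paste(missing, collapse = ", "),
            class = "strugglescope_named_point_error")
    sel <- raw$points[unname(point_map)]
    names(sel) <- names(point_map)
    raw$points <- sel
  }
  positions <- list()
  confidence <- list()
  has_conf <- FALSE
  for (nm in names(raw$points)) {
    p <- raw$points[[nm]]
    xy <- cbind(x = p$x, y = p$y)
    if (!is.null(p$conf)) {
      has_conf <- TRUE
      confidence[[nm]] <- p$conf
      if (!is.null(conf_threshold)) {
        xy <- .interp_low_confidence(xy, p$conf, conf_threshold)
      }
    }
    if (any(!is.finite(xy))) {
      xy[, 1L] <- .fill_linear(xy[, 1L])
      xy[, 2L] <- .fill_linear(xy[, 2L])
    }
    positions[[nm]] <- xy
  }
  pose_track(positions, fps = fps,
             confidence = if (has_conf) confidence else NULL)
}

.read_pose_dlc <- function(path, sep) {
  tab <- utils::read.table(path, sep = sep, header = FALSE, skip = 3L,
                           stringsAsFactors = FALSE)
  hdr <- utils::read.table(path, sep = sep, header = FALSE, nrows = 3L,
                           stringsAsFactors = FALSE, colClasses = "character")
  bodyparts <- as.character(hdr[2L, -1L])
  coords <- tolower(as.character(hdr[3L, -1L]))
  frame <- as.numeric(tab[[1L]])
  points <- list()
  for (bp in unique(bodyparts)) {
    jj <- which(bodyparts == bp) + 1L  # offset for frame column
    cc <- coords[bodyparts == bp]
    get1 <- function(role) {
      k <- jj[match(role, cc)]
      if (is.na(k)) NULL else as.numeric(tab[[k]])
    }
    x <- get1("x"); y <- get1("y")
    if (is.null(x) || is.null(y))
      stopf("body part '%s' lacks x/y columns", bp,
            class = "strugglescope_format_error")
    points[[bp]] <- list(x = x, y = y, conf = get1("likelihood"))
  }
  list(points = points, frame = frame)
}

.read_pose_flat <- function(path, sep) {
  tab <- utils::read.table(path, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE)
  need <- c("frame", "point", "x", "y")
  if (!all(need %in% names(tab)))
    stopf("flat pose table must have columns frame, point, x, y",
          class = "strugglescope_format_error")
  points <- list()
  frames <- sort(unique(tab$frame))
  for (pt in unique(tab$point)) {
    sub <- tab[tab$point == pt, , drop = FALSE]
    sub <- sub[order(sub$frame), , drop = FALSE]
    if (!identical(as.numeric(sub$frame), as.numeric(frames)))
      stopf("point '%s' is missing frames or has duplicates", pt,
            class = "strugglescope_format_error")
    points[[pt]] <- list(x = sub$x, y = sub$y,
                         conf = if ("confidence" %in% names(tab)) sub$confidence else NULL)
  }
  list(points = points, frame = frames)
}

.interp_low_confidence <- function(xy, conf, threshold) {
  bad <- conf < threshold
  if (!any(bad)) return(xy)
  if (all(bad)) stopf("no frames above the confidence threshold")
  xy[bad, ] <- NA_real_
  xy[, 1L] <- .fill_linear(xy[, 1L])
  xy[, 2L] <- .fill_linear(xy[, 2L])
  xy
}

.fill_linear <- function(v) {
  ok <- is.finite(v)
  if (all(ok)) return(v)
  idx <- seq_along(v)
  stats::approx(idx[ok], v[ok], xout = idx, rule = 2)$y
}

#' Per-frame speeds of tracked points
#'
#' Converts x/y positions into the speed of movement of each point during
#' each frame: the Euclidean distance traveled between consecutive frames,
#' in pixels/frame. The first frame has no predecessor and its speed is
#' defined as 0.
#'
#' @param track a [pose_track()].
#' @return an object of class `speed_series`: a list with `speeds` (frames
#'   x points numeric matrix) and `fps`.
#' @export
compute_speeds <- function(track) {
  stopifnot(inherits(track, "pose_track"))
  if (n_frames(track) < 2L)
    stopf("need at least 2 frames to compute speeds",
          class = "strugglescope_insufficient_data")
  speeds <- vapply(track$positions, function(m) {
    d <- sqrt(diff(m[, 1L])^2 + diff(m[, 2L])^2)
    c(0, d)
  }, numeric(n_frames(track)))
  structure(list(speeds = speeds, fps = track$fps), class = "speed_series")
}

#' Adaptive mobility threshold for one tracked point
#'
#' Computes the speed above which a point is considered mobile, from the
#' session's own speed distribution: take the subset of frame speeds at or
#' below the `q` quantile (linear-interpolation quantile, R type 7) and set
#' the threshold `k` standard deviations (n-1 denominator) above that
#' subset's mean. Normalizing to the session's own speeds rather than a raw
#' pixel threshold accommodates changes in camera distance and device
#' placement between trials. The conventions for the head fiber are
#' `q = 0.95, k = 1`; for the tail tip `q = 0.99, k = 3` (see
#' [mobility_config()]).
#'
#' `method = "quantile_sd"` instead anchors the threshold at the `q`
#' quantile itself (`quantile + k*sd(subset)`); the default `"mean_sd"`
#' reading is used throughout the package.
#'
#' @param speeds numeric vector of one point's frame speeds (pixels/frame).
#' @param q quantile in (0, 1] defining the "bottom" subset.
#' @param k standard-deviation multiplier, `k >= 0`.
#' @param method `"mean_sd"` (default) or `"quantile_sd"`.
#' @return scalar threshold in pixels/frame with attributes `q`, `k`,
#'   `method`.
#' @export
compute_mobility_threshold <- function(speeds, q = 0.95, k = 1,
                                       method = c("mean_sd", "quantile_sd")) {
  method <- match.arg(method)
  if (length(speeds) < 10L)
    stopf("need at least 10 frames of speeds")
  if (!is.numeric(q) || q <= 0 || q > 1) stopf("`q` must be in (0, 1]")
  if (!is.numeric(k) || k < 0) stopf("`k` must be >= 0")
  qv <- stats::quantile(speeds, q, names = FALSE, type = 7)
  S <- speeds[speeds <= qv]
  if (length(S) == 0L)
    stopf("empty sub-quantile subset", class = "strugglescope_degenerate_input")
  s <- if (length(S) >= 2L) stats::sd(S) else 0
  thr <- switch(method,
    mean_sd = mean(S) + k * s,
    quantile_sd = qv + k * s
  )
  structure(thr, q = q, k = k, method = method)
}

#' Default per-point mobility threshold configuration
#'
#' @param head_fiber,tail_tip lists with elements `q` and `k` for the two
#'   canonical points.
#' @param ... further named points, each a `list(q =, k =)`.
#' @param method threshold construction passed to
#'   [compute_mobility_threshold()].
#' @return named list of per-point configurations.
#' @export
mobility_config <- function(head_fiber = list(q = 0.95, k = 1),
                            tail_tip = list(q = 0.99, k = 3),
                            ..., method = "mean_sd") {
  cfg <- c(list(head_fiber = head_fiber, tail_tip = tail_tip), list(...))
  attr(cfg, "method") <- method
  cfg
}

#' Classify frames as mobile or immobile
#'
#' Applies per-point adaptive thresholds to a speed series: a frame is
#' mobile for a point iff its speed is strictly greater than that point's
#' threshold.
#'
#' @param speeds a `speed_series` from [compute_speeds()].
#' @param cfg per-point threshold configuration, see [mobility_config()].
#'   Points present in the series but absent from `cfg` fall back to the
#'   head-fiber convention (`q = 0.95, k = 1`).
#' @return an object of class `mobility_series`: list with `mobile`
#'   (frames x points logical matrix), `thresholds` (named numeric,
#'   pixels/frame), and `fps`.
#' @export
classify_mobility <- function(speeds, cfg = mobility_config()) {
  stopifnot(inherits(speeds, "speed_series"))
  method <- attr(cfg, "method") %||% "mean_sd"
  pts <- colnames(speeds$speeds)
  thresholds <- numeric(length(pts))
  names(thresholds) <- pts
  mobile <- matrix(FALSE, nrow(speeds$speeds), length(pts),
                   dimnames = list(NULL, pts))
  for (pt in pts) {
    pc <- cfg[[pt]] %||% list(q = 0.95, k = 1)
    thr <- compute_mobility_threshold(speeds$speeds[, pt], q = pc$q, k = pc$k,
                                      method = method)
    thresholds[pt] <- as.numeric(thr)
    mobile[, pt] <- speeds$speeds[, pt] > thresholds[pt]
  }
  structure(
    list(mobile = mobile, thresholds = thresholds, fps = speeds$fps,
         config = cfg),
    class = "mobility_series"
  )
}
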