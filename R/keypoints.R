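#' 2D keypoint sequences
#'
#' A `keypoint_seq` holds a fixed-rate sequence of 18-keypoint 2D body
#' skeletons with per-keypoint detection confidences, as produced by a
#' markerless pose estimator. Keypoint indices follow the standard 18-point
#' body map (0 = nose, 1 = neck, 2-4 right arm, 5-7 left arm, 8 = right hip,
#' 9 = right knee, 10 = right ankle, 11 = left hip, 12 = left knee,
#' 13 = left ankle, 14-17 eyes/ears). A missing detection is encoded as
#' confidence 0; its coordinates carry no meaning.
#'
#' @param x,y numeric matrices, frames x 18, pixel coordinates (image
#'   convention: origin top-left, y grows downward).
#' @param conf numeric matrix, frames x 18, confidences in \[0, 1\].
#' @param fps frames per second (> 0).
#' @param view camera view, `"frontal"` (subject walks toward the camera,
#'   coronal plane) or `"lateral"` (sagittal plane).
#' @param source_id free-text identifier for provenance.
#' @return An object of class `keypoint_seq`.
#' @export
keypoint_seq <- function(x, y, conf, fps, view = c("frontal", "lateral"),
                         source_id = "unknown") {
  view <- match.arg(view)
  x <- as.matrix(x); y <- as.matrix(y); conf <- as.matrix(conf)
  if (ncol(x) != 18L || !identical(dim(x), dim(y)) || !identical(dim(x), dim(conf)))
    stop("x, y, conf must be frames x 18 matrices of identical shape")
  stopifnot_scalar_num(fps, "fps", 0, strict_min = TRUE)
  if (any(conf < 0 | conf > 1, na.rm = TRUE))
    stop("confidences must lie in [0, 1]")
  bad <- conf > 0 & (!is.finite(x) | !is.finite(y))
  if (any(bad))
    stop("non-finite coordinates with positive confidence")
  structure(
    list(x = unname(x), y = unname(y), conf = unname(conf),
         fps = as.numeric(fps), view = view, source_id = source_id),
    class = "keypoint_seq"
  )
}

#' @export
print.keypoint_seq <- function(x, ...) {
  cat(sprintf("<keypoint_seq> %d frames @ %g fps (%.2f s), view = %s, source = %s\n",
              n_frames(x), x$fps, (n_frames(x) - 1) / x$fps, x$view, x$source_id))
  cat(sprintf("  detected keypoint-frames: %.1f%%\n", 100 * mean(x$conf > 0)))
  invisible(x)
}

#' @export
#' @rdname keypoint_seq
n_frames <- function(seq) nrow(seq$x)

# 1-based column for a 0-based keypoint index
kp_col <- function(kp) kp + 1L

#' Read per-frame pose-estimator JSON files
#'
#' Parses the standard per-frame JSON layout written by markerless pose
#' estimators: a top-level `people` array whose entries carry a flat
#' `pose_keypoints_2d` (or `pose_keypoints`) list of x, y, confidence
#' triples. One file corresponds to one video frame; files are read in
#' order of their numeric suffix (falling back to lexicographic order).
#' When several people are detected in a frame, the person with the largest
#' mean keypoint confidence is kept (the recordings follow a single walking
#' subject). A frame with an empty `people` array becomes an all-missing
#' frame (all confidences 0).
#'
#' @param paths character vector of JSON file paths, one per frame.
#' @param fps frame rate of the source video.
#' @param view camera view, see [keypoint_seq()].
#' @param source_id provenance tag; defaults to the common directory name.
#' @return A [keypoint_seq()].
#' @export
read_pose_json <- function(paths, fps, view = c("frontal", "lateral"),
                           source_id = NULL) {
  view <- match.arg(view)
  if (!length(paths)) stop("no input files")
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("input file not found: ", missing[[1]])
  # numeric-suffix order when available, else lexicographic
  num <- suppressWarnings(as.numeric(sub("^.*?(\\d+)\\D*$", "\\1", basename(paths))))
  ord <- if (!anyNA(num)) order(num, basename(paths)) else order(basename(paths))
  paths <- paths[ord]

  n <- length(paths)
  x <- matrix(0, n, 18L); y <- matrix(0, n, 18L); conf <- matrix(0, n, 18L)
  for (i in seq_len(n)) {
    obj <- tryCatch(jsonlite::fromJSON(paths[[i]], simplifyVector = FALSE),
                    error = function(e)
                      stop(sprintf("malformed JSON in '%s': %s", paths[[i]],
                                   conditionMessage(e)), call. = FALSE))
    people <- obj$people %||% list()
    if (!length(people)) next
    best <- NULL; best_mean <- -Inf
    for (p in people) {
      kp <- p$pose_keypoints_2d %||% p$pose_keypoints
      if (is.null(kp))
        stop(sprintf("no pose keypoints in '%s'", paths[[i]]), call. = FALSE)
      kp <- as.numeric(unlist(kp))
      if (length(kp) %% 3L != 0L)
        stop(sprintf("keypoint triple list in '%s' has length %d, not a multiple of 3",
                     paths[[i]], length(kp)), call. = FALSE)
      m <- matrix(kp, ncol = 3L, byrow = TRUE)
      if (nrow(m) < 18L)
        stop(sprintf("fewer than 18 keypoints in '%s'", paths[[i]]), call. = FALSE)
      m <- m[1:18, , drop = FALSE]
      if (mean(m[, 3]) > best_mean) { best <- m; best_mean <- mean(m[, 3]) }
    }
    x[i, ] <- best[, 1]; y[i, ] <- best[, 2]; conf[i, ] <- best[, 3]
  }
  # a zero-confidence slot's coordinates are meaningless; zero them for tidiness
  x[conf == 0] <- 0; y[conf == 0] <- 0
  keypoint_seq(x, y, conf, fps, view,
               source_id %||% basename(dirname(paths[[1]])))
}

#' Read/write keypoint sequences in long CSV form
#'
#' The CSV dialect has one row per (frame, keypoint) pair with columns
#' `frame`, `kp_index` (0-17), `x`, `y`, `confidence`. Pairs absent from the
#' file get confidence 0. Row order is irrelevant.
#'
#' @param path CSV file path.
#' @inheritParams read_pose_json
#' @return `read_keypoint_csv()` returns a [keypoint_seq()];
#'   `write_keypoint_csv()` invisibly returns `path`.
#' @export
read_keypoint_csv <- function(path, fps, view = c("frontal", "lateral"),
                              source_id = NULL) {
  view <- match.arg(view)
  df <- utils::read.csv(path)
  need <- c("frame", "kp_index", "x", "y", "confidence")
  if (!all(need %in% names(df)))
    stop("CSV must have columns: ", paste(need, collapse = ", "))
  if (any(df$kp_index < 0L | df$kp_index > 17L))
    stop("kp_index outside 0-17 in ", path)
  frames <- seq(min(df$frame), max(df$frame))
  n <- length(frames)
  x <- matrix(0, n, 18L); y <- matrix(0, n, 18L); conf <- matrix(0, n, 18L)
  ri <- match(df$frame, frames)
  ci <- df$kp_index + 1L
  idx <- cbind(ri, ci)
  x[idx] <- df$x; y[idx] <- df$y; conf[idx] <- df$confidence
  x[conf == 0] <- 0; y[conf == 0] <- 0
  keypoint_seq(x, y, conf, fps, view,
               source_id %||% sub("\\.csv$", "", basename(path)))
}

#' @param seq a [keypoint_seq()].
#' @rdname read_keypoint_csv
#' @export
write_keypoint_csv <- function(seq, path) {
  n <- n_frames(seq)
  df <- data.frame(
    frame = rep(0:(n - 1L), each = 18L),
    kp_index = rep(0:17, times = n),
    x = as.vector(t(seq$x)),
    y = as.vector(t(seq$y)),
    confidence = as.vector(t(seq$conf))
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Fill short detection dropouts by linear interpolation
#'
#' For each keypoint channel, runs of confidence-0 frames no longer than
#' `max_gap_s` that are flanked by detections on both sides are filled by
#' linear interpolation of x and y; the filled confidence is the mean of the
#' two flanking confidences. Longer runs (and runs touching the sequence
#' boundary) stay at confidence 0 and propagate as invalid downstream.
#'
#' @param seq a [keypoint_seq()].
#' @param max_gap_s longest gap, in seconds, that may be bridged (default
#'   0.2 s; a couple of frames of estimator flicker at typical frame rates).
#' @return A [keypoint_seq()] with short gaps filled.
#' @export
clean_and_interpolate <- function(seq, max_gap_s = 0.2) {
  stopifnot_scalar_num(max_gap_s, "max_gap_s", 0)
  n <- n_frames(seq)
  x <- seq$x; y <- seq$y; conf <- seq$conf
  for (k in 1:18) {
    miss <- conf[, k] == 0
    if (!any(miss)) next
    if (all(miss)) {
      warning(sprintf("keypoint %d never detected; channel left invalid", k - 1L))
      next
    }
    r <- rle(miss)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in seq_along(r$lengths)) {
      if (!r$values[j]) next
      a <- starts[j]; b <- ends[j]
      if (a == 1L || b == n) next            # boundary gap: no flank
      if (r$lengths[j] / seq$fps > max_gap_s) next
      lo <- a - 1L; hi <- b + 1L
      w <- (a:b - lo) / (hi - lo)
      x[a:b, k] <- x[lo, k] + w * (x[hi, k] - x[lo, k])
      y[a:b, k] <- y[lo, k] + w * (y[hi, k] - y[lo, k])
      conf[a:b, k] <- mean(c(conf[lo, k], conf[hi, k]))
    }
  }
  keypoint_seq(x, y, conf, seq$fps, seq$view, seq$source_id)
}

#' Resample a keypoint sequence to a higher frame rate
#'
#' Coordinate and confidence channels are linearly interpolated onto a
#' uniform grid at `target_fps` spanning the original time range. New
#' samples whose bracketing original frames include a missing detection
#' (confidence 0) are themselves marked missing, so interpolation never
#' fabricates coordinates across a dropout. Downsampling is not supported.
#'
#' @param seq a [keypoint_seq()].
#' @param target_fps output frame rate (>= `seq$fps`); default 100, which
#'   gives the cadence stage a 0.01 s lag resolution.
#' @return A [keypoint_seq()] at `target_fps`.
#' @export
resample_keypoints <- function(seq, target_fps = 100) {
  stopifnot_scalar_num(target_fps, "target_fps", 0, strict_min = TRUE)
  if (target_fps < seq$fps)
    stop("downsampling unsupported: target_fps < seq fps")
  n <- n_frames(seq)
  t_old <- (0:(n - 1L)) / seq$fps
  t_new <- seq(0, t_old[n], by = 1 / target_fps)
  m <- length(t_new)
  x <- matrix(0, m, 18L); y <- matrix(0, m, 18L); conf <- matrix(0, m, 18L)
  # bracketing original indices for each new sample
  lo <- pmin(pmax(findInterval(t_new, t_old), 1L), n)
  hi <- pmin(lo + 1L, n)
  on_grid <- abs(t_new - t_old[lo]) < 1e-9
  hi[on_grid] <- lo[on_grid]
  for (k in 1:18) {
    ok_chan <- seq$conf[, k] > 0
    if (!any(ok_chan)) next
    x[, k] <- stats::approx(t_old, seq$x[, k], xout = t_new, rule = 2)$y
    y[, k] <- stats::approx(t_old, seq$y[, k], xout = t_new, rule = 2)$y
    conf[, k] <- stats::approx(t_old, seq$conf[, k], xout = t_new, rule = 2)$y
    drop <- !ok_chan[lo] | !ok_chan[hi]
    conf[drop, k] <- 0
  }
  x[conf == 0] <- 0; y[conf == 0] <- 0
  keypoint_seq(x, y, conf, target_fps, seq$view, seq$source_id)
}
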