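#' Gait feature series
#'
#' A `feature_series` is a 1-D gait signal on a uniform time grid derived
#' from a keypoint sequence: either `LRang`, the angle in degrees between
#' the right hip-to-ankle vector and the left hip-to-ankle vector, or
#' `LRdiff`, the dimensionless difference between the left/right and
#' right/left projected leg-length ratios. In a lateral view LRang completes
#' one oscillation per step; in a frontal view LRdiff completes one
#' oscillation per gait cycle (two steps).
#'
#' @param t time grid in seconds (uniform, step 1/`fps`).
#' @param v feature values (degrees for LRang, dimensionless for LRdiff).
#' @param fps sampling rate in Hz.
#' @param kind `"LRang"` or `"LRdiff"`.
#' @param valid logical mask; FALSE where the source keypoints were invalid.
#' @param view camera view the feature was computed from.
#' @return An object of class `feature_series`.
#' @export
feature_series <- function(t, v, fps, kind = c("LRang", "LRdiff"),
                           valid = rep(TRUE, length(v)),
                           view = c("frontal", "lateral")) {
  kind <- match.arg(kind); view <- match.arg(view)
  if (length(t) != length(v) || length(v) != length(valid))
    stop("t, v, valid must have equal length")
  if (length(t) > 1L && max(abs(diff(t) - 1 / fps)) > 1e-6 / fps)
    stop("t must be a uniform grid with step 1/fps")
  structure(list(t = as.numeric(t), v = as.numeric(v), fps = as.numeric(fps),
                 kind = kind, valid = as.logical(valid), view = view),
            class = "feature_series")
}

#' @export
print.feature_series <- function(x, ...) {
  cat(sprintf("<feature_series> %s (%s view): %d samples @ %g Hz, %.1f%% valid\n",
              x$kind, x$view, length(x$v), x$fps, 100 * mean(x$valid)))
  invisible(x)
}

#' @export
plot.feature_series <- function(x, ...) {
  v <- x$v; v[!x$valid] <- NA
  ylab <- if (x$kind == "LRang") "LRang (deg)" else "LRdiff"
  graphics::plot(x$t, v, type = "l", xlab = "time (s)", ylab = ylab, ...)
  invisible(x)
}

# legs as 2 x n matrices of (dx, dy); returns list(r, l, ok)
leg_vectors <- function(seq, conf_floor) {
  cols <- kp_col(c(8L, 10L, 11L, 13L))  # right hip, right ankle, left hip, left ankle
  ok <- rowSums(seq$conf[, cols, drop = FALSE] > conf_floor) == 4L
  list(
    rx = seq$x[, cols[2]] - seq$x[, cols[1]],
    ry = seq$y[, cols[2]] - seq$y[, cols[1]],
    lx = seq$x[, cols[4]] - seq$x[, cols[3]],
    ly = seq$y[, cols[4]] - seq$y[, cols[3]],
    ok = ok
  )
}

#' Inter-leg angle signal (LRang)
#'
#' Per frame, the angle between the vector from right hip (keypoint 8) to
#' right ankle (keypoint 10) and the vector from left hip (keypoint 11) to
#' left ankle (keypoint 13):
#' \deqn{\mathrm{LRang} = \arccos\left(\frac{\vec{u}_R \cdot \vec{u}_L}
#'   {|\vec{u}_R|\,|\vec{u}_L|}\right), \quad 0 \le \mathrm{LRang} \le 180^\circ.}
#' Frames in which any of the four keypoints is missing, or in which a hip
#' and its ankle coincide (zero-length leg vector), are masked invalid
#' rather than clamped. The arccos argument is clipped to \[-1, 1\] to
#' absorb floating-point rounding.
#'
#' @param seq a [keypoint_seq()].
#' @param conf_floor confidences must exceed this for a keypoint to count as
#'   detected (default 0: trust every nonzero detection).
#' @return A [feature_series()] of kind `"LRang"`, in degrees.
#' @export
compute_lrang <- function(seq, conf_floor = 0) {
  lv <- leg_vectors(seq, conf_floor)
  nr <- sqrt(lv$rx^2 + lv$ry^2)
  nl <- sqrt(lv$lx^2 + lv$ly^2)
  ok <- lv$ok & nr > 0 & nl > 0
  cosang <- (lv$rx * lv$lx + lv$ry * lv$ly) / (nr * nl)
  v <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
  v[!ok] <- NA_real_
  n <- n_frames(seq)
  feature_series((0:(n - 1L)) / seq$fps, ifelse(ok, v, 0), seq$fps,
                 "LRang", valid = ok, view = seq$view)
}

#' Bilateral leg-length-ratio difference signal (LRdiff)
#'
#' Per frame, with \eqn{R = |\vec{u}_R|} and \eqn{L = |\vec{u}_L|} the
#' projected right and left hip-to-ankle lengths in pixels:
#' \deqn{\mathrm{LRdiff} = \frac{L}{R} - \frac{R}{L}.}
#' LRdiff is 0 when the projected legs are equally long, positive when the
#' left leg projects longer, and is exactly negated when left and right are
#' swapped. Invalid or zero-length legs mask the frame.
#'
#' @inheritParams compute_lrang
#' @return A [feature_series()] of kind `"LRdiff"`, dimensionless.
#' @export
compute_lrdiff <- function(seq, conf_floor = 0) {
  lv <- leg_vectors(seq, conf_floor)
  nr <- sqrt(lv$rx^2 + lv$ry^2)
  nl <- sqrt(lv$lx^2 + lv$ly^2)
  ok <- lv$ok & nr > 0 & nl > 0
  v <- ifelse(ok, nl / nr - nr / nl, 0)
  n <- n_frames(seq)
  feature_series((0:(n - 1L)) / seq$fps, v, seq$fps,
                 "LRdiff", valid = ok, view = seq$view)
}

#' Zero-phase band-pass filter for gait feature signals
#'
#' Band-pass with the two-pass (forward-backward) magnitude response of an
#' order-4 Butterworth design, applied spectrally so the filter is exactly
#' zero-phase and exactly linear: peak timings that feed the windowed
#' autocorrelation downstream are not shifted, and DC is rejected outright.
#' The bilinear-prewarped squared magnitude
#' \deqn{|H(f)|^2 = \left[1 + \left(\frac{w^2 - w_1 w_2}{w\,(w_2 - w_1)}
#'   \right)^{8}\right]^{-1}, \quad w = \tan(\pi f / f_s),}
#' is applied to the FFT of the (odd-reflection padded) signal. The default
#' band 0.1-7 Hz keeps locomotor and tremor-band content while removing
#' baseline drift and estimator jitter above 7 Hz. Invalid samples are
#' bridged by linear interpolation before filtering and re-masked after.
#'
#' @param series a [feature_series()].
#' @param low_hz,high_hz band edges in Hz; `high_hz` must be below the
#'   Nyquist frequency `fps/2`.
#' @return The filtered [feature_series()] (same grid, same validity mask).
#' @export
bandpass <- function(series, low_hz = 0.1, high_hz = 7.0) {
  fps <- series$fps
  if (high_hz >= fps / 2)
    stop("high_hz must be below the Nyquist frequency fps/2")
  if (low_hz <= 0 || low_hz >= high_hz)
    stop("need 0 < low_hz < high_hz")
  v <- series$v
  if (!any(series$valid)) stop("no valid samples to filter")
  if (!all(series$valid)) {
    ok <- which(series$valid)
    v <- stats::approx(series$t[ok], v[ok], xout = series$t, rule = 2)$y
  }
  n <- length(v)
  # odd-reflection padding against circular wrap-around at the record edges
  p <- min(n - 1L, round(2 * fps / low_hz))
  left <- 2 * v[1] - v[(p + 1L):2L]
  right <- 2 * v[n] - v[(n - 1L):(n - p)]
  xp <- c(left, v, right)
  m <- length(xp)
  f <- c(0:(m %/% 2), -((m - m %/% 2 - 1):1)) * fps / m
  w <- tan(pi * f / fps)
  w1 <- tan(pi * low_hz / fps); w2 <- tan(pi * high_hz / fps)
  q <- (w^2 - w1 * w2) / (w * (w2 - w1))
  q[!is.finite(q)] <- Inf                      # DC and Nyquist: fully rejected
  gain <- 1 / (1 + q^8)                        # one Butterworth pass ...
  out <- Re(stats::fft(stats::fft(xp) * gain^2, inverse = TRUE)) / m  # ... twice
  out <- out[(p + 1L):(p + n)]
  feature_series(series$t, out, fps, series$kind,
                 valid = series$valid, view = series$view)
}

#' Write/read a feature series as CSV
#'
#' Three columns: `t` (seconds), `value`, `valid` (0/1).
#' @param series a [feature_series()].
#' @param path CSV path.
#' @export
write_feature_csv <- function(series, path) {
  utils::write.csv(
    data.frame(t = series$t, value = series$v, valid = as.integer(series$valid)),
    path, row.names = FALSE)
  invisible(path)
}

#' @param kind,view metadata for the series being read back.
#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(path, kind = c("LRang", "LRdiff"),
                             view = c("frontal", "lateral")) {
  df <- utils::read.csv(path)
  if (!all(c("t", "value", "valid") %in% names(df)))
    stop("feature CSV must have columns t, value, valid")
  dt <- diff(df$t)
  fps <- 1 / stats::median(dt)
  feature_series(df$t, df$value, fps, match.arg(kind),
                 valid = df$valid > 0, view = match.arg(view))
}
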