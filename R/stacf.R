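#' Short-time autocorrelation (ST-ACF) of a gait feature signal
#'
#' Slides a window of length `window_s` along the signal in steps of
#' `shift_s` and computes, for each window, a normalized autocorrelation
#' over lags 0 .. `window_s` (lag step 1/fps). Each segment is mean-removed
#' and Hann-tapered; lag products are then compensated by the taper's own
#' overlap energy at the same lag, so that a pure oscillation keeps its
#' autocorrelation peak at the true period instead of having it dragged
#' toward shorter lags by the taper envelope. Values are scaled so r(0) = 1;
#' because of the compensation they can exceed 1 in magnitude at lags
#' approaching the window length, where the taper overlap energy vanishes
#' (the run structure of the peak-selection rule keeps that region out of
#' the lag choice in practice). Windows overlapping any invalid sample are
#' marked invalid (their curves are NA).
#'
#' Autocorrelation is preferred over the short-time Fourier transform here
#' because its frequency resolution at these window lengths is the lag step
#' (0.01 s at 100 fps), whereas an STFT bin is 1/`window_s` wide (0.5 Hz for
#' a 2 s window) - far too coarse to resolve gait frequency.
#'
#' @param series a [feature_series()].
#' @param window_s window length in seconds: 2.0 for normal gait, 3.0 for
#'   pathological gait (so that 2-3 steps fit in a window even at low
#'   cadence).
#' @param shift_s hop between consecutive windows, default 0.01 s (one
#'   sample at 100 fps).
#' @return An object of class `stacf`: list with `acf` (lags x windows
#'   matrix), `lags_s`, `t_centers`, `window_s`, `shift_s`, `fps`, `n_eff`
#'   (taper-effective samples per window, `(sum h^2)^2 / sum h^4`, about
#'   half the raw count for a Hann taper), `window_valid`, and the source
#'   `kind`/`view`.
#' @export
st_acf <- function(series, window_s, shift_s = 0.01) {
  fps <- series$fps
  stopifnot_scalar_num(window_s, "window_s", 0, strict_min = TRUE)
  stopifnot_scalar_num(shift_s, "shift_s", 0, strict_min = TRUE)
  if (fps * shift_s < 1 - 1e-9)
    stop("shift_s must be at least one sample (fps * shift_s >= 1)")
  n <- length(series$v)
  dur <- (n - 1L) / fps
  if (dur < window_s)
    stop(sprintf("series duration %.2f s is shorter than window_s = %g s", dur, window_s))
  L <- round(window_s * fps) + 1L          # lags 0 .. window_s inclusive
  hop <- round(shift_s * fps)
  starts <- seq(1L, n - L + 1L, by = hop)
  W <- length(starts)

  seg_idx <- outer(0:(L - 1L), starts, `+`)     # L x W index matrix
  segs <- matrix(series$v[seg_idx], L, W)
  win_valid <- colSums(matrix(!series$valid[seg_idx], L, W)) == 0L

  h <- hann_taper(L)
  segs <- sweep(segs, 2L, colMeans(segs)) * h

  nfft <- 2^ceiling(log2(2L * L))
  pad <- matrix(0, nfft - L, W)
  A <- stats::mvfft(rbind(segs, pad))
  raw <- Re(stats::mvfft(A * Conj(A), inverse = TRUE))[1:L, , drop = FALSE]
  ah <- stats::fft(c(h, rep(0, nfft - L)))
  taper_energy <- Re(stats::fft(ah * Conj(ah), inverse = TRUE))[1:L]
  # taper compensation, then scale each window so r(0) = 1
  acf <- raw / taper_energy * taper_energy[1]
  denom <- rep(acf[1, ], each = L)
  acf <- matrix(acf / denom, L, W)
  acf[, !win_valid] <- NA_real_

  structure(list(
    acf = acf,
    lags_s = (0:(L - 1L)) / fps,
    t_centers = (starts - 1L) / fps + window_s / 2,
    window_s = window_s, shift_s = hop / fps, fps = fps,
    # taper-effective sample count: the white-noise CI 1.96/sqrt(n_eff) is
    # only nominal if n_eff accounts for the Hann weighting
    n_eff = rep(sum(h^2)^2 / sum(h^4), W), window_valid = win_valid,
    kind = series$kind, view = series$view
  ), class = "stacf")
}

#' @export
print.stacf <- function(x, ...) {
  cat(sprintf("<stacf> %d windows of %g s (shift %g s), %d lags @ %g fps; %d valid\n",
              length(x$t_centers), x$window_s, x$shift_s, length(x$lags_s),
              x$fps, sum(x$window_valid)))
  invisible(x)
}

#' @export
plot.stacf <- function(x, ...) {
  graphics::image(x$t_centers, x$lags_s, t(x$acf),
                  xlab = "window center (s)", ylab = "lag (s)",
                  col = grDevices::hcl.colors(64, "RdBu", rev = TRUE),
                  zlim = c(-1, 1), ...)
  invisible(x)
}

#' Short-time Fourier magnitude spectrogram (diagnostic)
#'
#' Hann-windowed magnitude spectrogram on the same window grid as
#' [st_acf()]. Kept as a comparison view only: its frequency bins are
#' 1/`window_s` apart, too coarse for gait-frequency estimation at usable
#' window lengths.
#'
#' @inheritParams st_acf
#' @return List with `mag` (freqs x windows), `freqs_hz`, `t_centers`,
#'   `window_s`, `shift_s`, `fps`; class `stfft`.
#' @export
st_fft <- function(series, window_s, shift_s = 0.01) {
  fps <- series$fps
  if (fps * shift_s < 1 - 1e-9)
    stop("shift_s must be at least one sample (fps * shift_s >= 1)")
  n <- length(series$v)
  if ((n - 1L) / fps < window_s)
    stop("series shorter than window_s")
  M <- round(window_s * fps)               # FFT length -> bin width 1/window_s
  hop <- round(shift_s * fps)
  starts <- seq(1L, n - M + 1L, by = hop)
  seg_idx <- outer(0:(M - 1L), starts, `+`)
  segs <- matrix(series$v[seg_idx], M, length(starts)) * hann_taper(M)
  spec <- stats::mvfft(segs)
  nb <- floor(M / 2) + 1L
  structure(list(
    mag = abs(spec[1:nb, , drop = FALSE]),
    freqs_hz = (0:(nb - 1L)) * fps / M,
    t_centers = (starts - 1L) / fps + window_s / 2,
    window_s = window_s, shift_s = hop / fps, fps = fps
  ), class = "stfft")
}

#' Select the gait lag from one window's autocorrelation curve
#'
#' Implements the second-positive-phase peak rule: scanning lags above
#' zero, the initial negative phase is the first maximal contiguous run of
#' r < 0; the secondary positive phase is the next maximal contiguous run
#' of r > 0. The selected lag maximizes r within that run intersected with
#' `[lag_min_s, lag_max_s]`; ties break toward the smaller lag (higher
#' frequency). The peak is flagged significant when it exceeds the
#' large-sample 95% white-noise confidence bound `1.96 / sqrt(n_eff)`.
#'
#' @param r numeric autocorrelation values over `lags_s` (r at lag 0 = 1).
#' @param lags_s lag grid in seconds, starting at 0.
#' @param n_eff number of samples behind the curve (for the CI bound).
#' @param lag_min_s,lag_max_s search band in seconds; the default mirrors
#'   the 0.1-7 Hz feature band (lags 1/7 to 10 s).
#' @param min_overlap_s lags closer than this to the end of the curve are
#'   never selected (default 0.25 s): there the autocorrelation is
#'   estimated from almost no overlapping samples and, with taper
#'   compensation, is numerically unreliable.
#' @return List with `lag_s` (NA when no negative phase or no subsequent
#'   positive phase lies in range) and `significant`.
#' @export
pick_gait_lag <- function(r, lags_s, n_eff, lag_min_s = 1 / 7, lag_max_s = 10,
                          min_overlap_s = 0.25) {
  stopifnot(length(r) == length(lags_s), lag_min_s < lag_max_s)
  none <- list(lag_s = NA_real_, significant = FALSE)
  lag_max_s <- min(lag_max_s, max(lags_s) - min_overlap_s)
  if (lag_max_s <= lag_min_s) return(none)
  if (anyNA(r)) return(none)
  s <- sign(r[-1L])                        # exclude lag 0
  i <- which(s < 0)[1L]
  if (is.na(i)) return(none)
  after <- which(s > 0 & seq_along(s) > i)
  # skip past the full initial negative run first
  neg_end <- i
  while (neg_end < length(s) && s[neg_end + 1L] < 0) neg_end <- neg_end + 1L
  j <- after[after > neg_end][1L]
  if (is.na(j)) return(none)
  k <- j
  while (k < length(s) && s[k + 1L] > 0) k <- k + 1L
  run <- j:k
  lag_run <- lags_s[-1L][run]
  keep <- run[lag_run >= lag_min_s & lag_run <= lag_max_s]
  if (!length(keep)) return(none)
  best <- keep[which.max(r[-1L][keep])]    # which.max: first max -> smaller lag
  list(lag_s = lags_s[-1L][best],
       significant = r[-1L][best] > 1.96 / sqrt(n_eff))
}

#' Estimate cadence from a short-time autocorrelation matrix
#'
#' Applies [pick_gait_lag()] to every valid window, takes the median lag
#' over windows whose peak is significant, converts it to a gait-cycle
#' frequency (with the x0.5 correction for lateral views, where the
#' inter-leg angle completes one cycle per step, i.e. two per gait cycle),
#' and reports cadence as 120 x gait frequency: one gait cycle comprises
#' two steps, so a 1 Hz gait frequency is a cadence of 120 steps/min.
#'
#' @param stacf an [st_acf()] result.
#' @param view `"frontal"` or `"lateral"`; defaults to the view recorded in
#'   `stacf`.
#' @inheritParams pick_gait_lag
#' @return An object of class `cadence_estimate`: `per_window` data frame
#'   (`t_center`, `lag_s`, `significant`, `freq_hz`), `representative_lag_s`,
#'   `representative_freq_hz`, `cadence_steps_per_min`, `view`, `window_s`.
#'   Errors (class `gaitacf_no_significant_window`) if no window has a
#'   significant peak; the per-window table rides on the condition for
#'   diagnosis.
#' @export
estimate_cadence <- function(stacf, view = stacf$view,
                             lag_min_s = 1 / 7, lag_max_s = 10,
                             min_overlap_s = 0.25) {
  view <- match.arg(view, c("frontal", "lateral"))
  W <- length(stacf$t_centers)
  lag <- rep(NA_real_, W); sig <- rep(FALSE, W)
  for (w in seq_len(W)) {
    if (!stacf$window_valid[w]) next
    p <- pick_gait_lag(stacf$acf[, w], stacf$lags_s, stacf$n_eff[w],
                       lag_min_s, lag_max_s, min_overlap_s)
    lag[w] <- p$lag_s; sig[w] <- p$significant
  }
  vf <- if (view == "lateral") 0.5 else 1.0
  per_window <- data.frame(
    t_center = stacf$t_centers, lag_s = lag, significant = sig,
    freq_hz = ifelse(is.na(lag), NA_real_, vf / lag)
  )
  if (!any(sig)) {
    cond <- structure(
      class = c("gaitacf_no_significant_window", "error", "condition"),
      list(message = "no window has a significant autocorrelation peak; cannot estimate cadence",
           call = sys.call(), per_window = per_window))
    stop(cond)
  }
  med_lag <- stats::median(lag[sig])
  freq <- vf / med_lag
  structure(list(
    per_window = per_window,
    representative_lag_s = med_lag,
    representative_freq_hz = freq,
    cadence_steps_per_min = 120 * freq,
    view = view, window_s = stacf$window_s,
    n_windows = W, n_valid = sum(stacf$window_valid), n_significant = sum(sig)
  ), class = "cadence_estimate")
}

#' @export
print.cadence_estimate <- function(x, ...) {
  cat(sprintf("<cadence_estimate> %.1f steps/min (gait frequency %.3f Hz, median lag %.2f s)\n",
              x$cadence_steps_per_min, x$representative_freq_hz, x$representative_lag_s))
  cat(sprintf("  view %s, window %g s; %d/%d windows significant\n",
              x$view, x$window_s, x$n_significant, x$n_windows))
  invisible(x)
}

#' @export
summary.cadence_estimate <- function(object, ...) {
  pw <- object$per_window
  sig_lags <- pw$lag_s[pw$significant]
  out <- list(
    cadence_steps_per_min = object$cadence_steps_per_min,
    representative_freq_hz = object$representative_freq_hz,
    view = object$view, window_s = object$window_s,
    n_windows = object$n_windows, n_valid = object$n_valid,
    n_significant = object$n_significant,
    lag_quartiles_s = stats::quantile(sig_lags, c(0.25, 0.5, 0.75), names = FALSE)
  )
  class(out) <- "summary.cadence_estimate"
  out
}

#' @export
print.summary.cadence_estimate <- function(x, ...) {
  cat(sprintf("Cadence: %.1f steps/min (%s view, %g s windows)\n",
              x$cadence_steps_per_min, x$view, x$window_s))
  cat(sprintf("Windows: %d total, %d valid, %d with significant peak\n",
              x$n_windows, x$n_valid, x$n_significant))
  cat(sprintf("Significant-lag quartiles: %.2f / %.2f / %.2f s\n",
              x$lag_quartiles_s[1], x$lag_quartiles_s[2], x$lag_quartiles_s[3]))
  invisible(x)
}

#' @export
plot.cadence_estimate <- function(x, ...) {
  pw <- x$per_window
  graphics::plot(pw$t_center, pw$lag_s, type = "p", pch = ifelse(pw$significant, 19, 1),
                 xlab = "window center (s)", ylab = "selected lag (s)", ...)
  graphics::abline(h = x$representative_lag_s, lty = 2)
  invisible(x)
}

#' Write an ST-ACF matrix as CSV (rows = windows, columns = lags)
#' @param stacf an [st_acf()] result.
#' @param path output CSV path.
#' @export
write_stacf_csv <- function(stacf, path) {
  m <- t(stacf$acf)
  colnames(m) <- sprintf("lag_%.4f", stacf$lags_s)
  df <- cbind(data.frame(t_center = stacf$t_centers), as.data.frame(m))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
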