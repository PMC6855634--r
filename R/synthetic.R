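#' Configuration for the synthetic gait generator
#'
#' The generator produces schematic 18-keypoint walking sequences whose
#' LRdiff (frontal view) and LRang (lateral view) signals have known
#' spectral content, so the whole pipeline can be exercised against ground
#' truth without video. Geometry is 2D-schematic: only the projected leg
#' lengths and the inter-leg angle are made faithful, because those are the
#' only quantities the analysis consumes.
#'
#' @param gait_freq_hz gait-cycle frequency in Hz (> 0); true cadence is
#'   120 x this value.
#' @param duration_s sequence duration in seconds.
#' @param fps frame rate of the generated sequence.
#' @param view `"frontal"` or `"lateral"`.
#' @param amplitude_growth multiplicative amplitude growth rate per second
#'   (the oscillation amplitude scales as exp(rate x t)), emulating a
#'   subject walking toward the camera.
#' @param noise_sd_px i.i.d. Gaussian pixel noise added to every keypoint
#'   coordinate (estimator jitter).
#' @param dropout_prob per keypoint-frame probability of a missed detection
#'   (confidence set to 0).
#' @param freeze_windows list of freeze episodes, each
#'   `list(start_s, end_s, tremor_hz, tremor_amp)`: inside a window the
#'   locomotor oscillation stops and is replaced by a tremor-band
#'   oscillation of relative amplitude `tremor_amp` at `tremor_hz`
#'   (default band 4-7 Hz, inside the 0.1-7 Hz analysis passband so the
#'   pipeline sees it). Windows must lie within the sequence and must not
#'   overlap.
#' @param amplitude_scale overall scale of the locomotor oscillation
#'   (1 = normal gait; reduced for shuffling gait).
#' @param freq_jitter relative gait-frequency wobble (0.1 = +-10%),
#'   realized as slow sinusoidal frequency modulation integrated into the
#'   phase.
#' @param seed integer seed; all randomness in the generated sequence
#'   derives from it.
#' @return A validated list of class `gait_sim_config`.
#' @export
gait_sim_config <- function(gait_freq_hz = 1.0, duration_s = 12, fps = 100,
                            view = c("frontal", "lateral"),
                            amplitude_growth = 0, noise_sd_px = 0,
                            dropout_prob = 0, freeze_windows = list(),
                            amplitude_scale = 1, freq_jitter = 0, seed = 1L) {
  view <- match.arg(view)
  stopifnot_scalar_num(gait_freq_hz, "gait_freq_hz", 0, strict_min = TRUE)
  stopifnot_scalar_num(duration_s, "duration_s", 0, strict_min = TRUE)
  stopifnot_scalar_num(fps, "fps", 0, strict_min = TRUE)
  stopifnot_scalar_num(noise_sd_px, "noise_sd_px", 0)
  if (dropout_prob < 0 || dropout_prob >= 1)
    stop("dropout_prob must lie in [0, 1)")
  fw <- lapply(freeze_windows, function(w) {
    w <- as.list(w)
    stopifnot(all(c("start_s", "end_s", "tremor_hz", "tremor_amp") %in% names(w)))
    if (w$start_s < 0 || w$end_s > duration_s || w$start_s >= w$end_s)
      stop("freeze window outside [0, duration_s] or empty")
    if (w$tremor_hz >= fps / 2)
      stop("tremor_hz must be below the Nyquist frequency fps/2")
    w
  })
  if (length(fw) > 1L) {
    ss <- order(vapply(fw, `[[`, numeric(1), "start_s"))
    fw <- fw[ss]
    for (i in seq_len(length(fw) - 1L))
      if (fw[[i]]$end_s > fw[[i + 1L]]$start_s)
        stop("freeze windows must not overlap")
  }
  structure(list(
    gait_freq_hz = gait_freq_hz, duration_s = duration_s, fps = fps,
    view = view, amplitude_growth = amplitude_growth,
    noise_sd_px = noise_sd_px, dropout_prob = dropout_prob,
    freeze_windows = fw, amplitude_scale = amplitude_scale,
    freq_jitter = freq_jitter, seed = as.integer(seed)
  ), class = "gait_sim_config")
}

# static schematic skeleton (pixels; image origin top-left, y downward)
skeleton_base <- function(view) {
  # nose neck rsho relb rwri lsho lelb lwri rhip rkne rank lhip lkne lank
  # reye leye rear lear
  x <- c(320, 320, 290, 280, 275, 350, 360, 365, 300, 300, 300, 340, 340, 340,
         312, 328, 305, 335)
  y <- c(80, 130, 135, 180, 225, 135, 180, 225, 260, 320, 380, 260, 320, 380,
         72, 72, 78, 78)
  if (view == "lateral") {
    # sagittal view: left and right sides nearly superposed
    x[c(3:5)] <- c(318, 316, 315); x[c(6:8)] <- c(322, 324, 325)
    x[9] <- 318; x[12] <- 322
    x[c(15, 17)] <- c(316, 310); x[c(16, 18)] <- c(324, 330)
  }
  list(x = x, y = y)
}

#' Simulate a walking sequence of 2D keypoints
#'
#' Builds ankle (and knee) trajectories so that the frontal-view LRdiff
#' signal is approximately `A(t) sin(2 pi f t)` - the projected leg lengths
#' oscillate in antiphase at the gait-cycle frequency - and the lateral-view
#' inter-leg angle oscillates at twice the gait-cycle frequency (one LRang
#' cycle per step). Inside freeze windows the locomotor oscillation
#' amplitude drops to zero and a tremor-band oscillation takes its place.
#' Gaussian pixel noise and random detection dropouts are applied last.
#'
#' @param config a [gait_sim_config()].
#' @return List with `seq` (a [keypoint_seq()]), and `truth`: the nominal
#'   `gait_freq_hz`, `cadence_steps_per_min` (= 120 x frequency), the
#'   per-frame logical `freeze_mask`, and the config used.
#' @export
simulate_gait <- function(config) {
  stopifnot(inherits(config, "gait_sim_config"))
  with_seed(config$seed, {
    fps <- config$fps
    n <- round(config$duration_s * fps) + 1L
    t <- (0:(n - 1L)) / fps
    f0 <- config$gait_freq_hz

    # instantaneous gait frequency with slow sinusoidal wobble
    if (config$freq_jitter > 0) {
      phi_j <- stats::runif(1, 0, 2 * pi)
      f_inst <- f0 * (1 + config$freq_jitter * sin(2 * pi * 0.15 * t + phi_j))
    } else {
      f_inst <- rep(f0, n)
    }
    phase <- 2 * pi * cumsum(f_inst) / fps

    amp <- config$amplitude_scale * exp(config$amplitude_growth * t)
    osc <- amp * sin(phase)

    freeze_mask <- rep(FALSE, n)
    for (w in config$freeze_windows) {
      idx <- t >= w$start_s & t < w$end_s
      freeze_mask[idx] <- TRUE
      osc[idx] <- w$tremor_amp * sin(2 * pi * w$tremor_hz * (t[idx] - w$start_s))
    }

    sk <- skeleton_base(config$view)
    x <- matrix(rep(sk$x, each = n), n, 18L)
    y <- matrix(rep(sk$y, each = n), n, 18L)

    L0 <- 120  # nominal projected leg length, px
    if (config$view == "frontal") {
      d <- pmin(pmax(0.1 * osc, -0.45), 0.45)   # antiphase leg-length modulation
      Lr <- L0 * (1 - d); Ll <- L0 * (1 + d)
      y[, kp_col(10L)] <- y[, kp_col(8L)] + Lr
      y[, kp_col(13L)] <- y[, kp_col(11L)] + Ll
      y[, kp_col(9L)]  <- y[, kp_col(8L)] + Lr / 2
      y[, kp_col(12L)] <- y[, kp_col(11L)] + Ll / 2
    } else {
      theta0 <- 15 * pi / 180                   # peak half-angle per leg
      thr <- theta0 * osc; thl <- -thr          # antiphase swing -> LRang at 2f
      x[, kp_col(10L)] <- x[, kp_col(8L)] + L0 * sin(thr)
      y[, kp_col(10L)] <- y[, kp_col(8L)] + L0 * cos(thr)
      x[, kp_col(13L)] <- x[, kp_col(11L)] + L0 * sin(thl)
      y[, kp_col(13L)] <- y[, kp_col(11L)] + L0 * cos(thl)
      x[, kp_col(9L)]  <- x[, kp_col(8L)] + L0 / 2 * sin(thr)
      y[, kp_col(9L)]  <- y[, kp_col(8L)] + L0 / 2 * cos(thr)
      x[, kp_col(12L)] <- x[, kp_col(11L)] + L0 / 2 * sin(thl)
      y[, kp_col(12L)] <- y[, kp_col(11L)] + L0 / 2 * cos(thl)
    }

    if (config$noise_sd_px > 0) {
      x <- x + matrix(stats::rnorm(n * 18L, sd = config$noise_sd_px), n, 18L)
      y <- y + matrix(stats::rnorm(n * 18L, sd = config$noise_sd_px), n, 18L)
    }
    conf <- matrix(pmin(pmax(stats::rnorm(n * 18L, 0.8, 0.05), 0.05), 1), n, 18L)
    if (config$dropout_prob > 0)
      conf[matrix(stats::runif(n * 18L) < config$dropout_prob, n, 18L)] <- 0
    x[conf == 0] <- 0; y[conf == 0] <- 0

    list(
      seq = keypoint_seq(x, y, conf, fps, config$view,
                         source_id = sprintf("sim_f%.2f_seed%d", f0, config$seed)),
      truth = list(gait_freq_hz = f0,
                   cadence_steps_per_min = 120 * f0,
                   freeze_mask = freeze_mask,
                   t = t,
                   config = config)
    )
  })
}

cohort_presets <- list(
  normal = list(freq_range = c(0.85, 1.15), amplitude_scale = 1.0,
                freq_jitter = 0.02, noise_sd_px = 1.0, dropout_prob = 0.01,
                freeze_frac = 0),
  mild   = list(freq_range = c(0.80, 1.20), amplitude_scale = 0.5,
                freq_jitter = 0.10, noise_sd_px = 1.5, dropout_prob = 0.02,
                freeze_frac = 0),
  severe = list(freq_range = c(0.60, 1.00), amplitude_scale = 0.4,
                freq_jitter = 0.20, noise_sd_px = 2.0, dropout_prob = 0.02,
                freeze_frac = c(0.45, 0.6))
)

#' Simulate a labeled three-group gait cohort
#'
#' Generates `normal` sequences (steady gait, light noise), `mild`
#' sequences (halved oscillation amplitude, +-10% frequency wobble - small
#' shuffling steps that are still periodic) and `severe` sequences (at
#' least 40% of the duration frozen with 4-7 Hz tremor, strong wobble,
#' further reduced amplitude - freezing-of-gait phenomenology). Group
#' parameters are drawn reproducibly from `seed`.
#'
#' @param n_normal,n_mild,n_severe group sizes (>= 0).
#' @param seed master seed; per-sequence seeds derive from it.
#' @param duration_s,fps,view passed to every sequence's config.
#' @return List of entries `list(seq, truth, label, id)`, one per sequence,
#'   with a `labels` attribute.
#' @export
simulate_cohort <- function(n_normal, n_mild, n_severe, seed = 1L,
                            duration_s = 12, fps = 100, view = "frontal") {
  counts <- c(normal = n_normal, mild = n_mild, severe = n_severe)
  stopifnot(all(counts >= 0))
  with_seed(seed, {
    out <- list()
    for (label in names(counts)) {
      preset <- cohort_presets[[label]]
      for (i in seq_len(counts[[label]])) {
        f0 <- stats::runif(1, preset$freq_range[1], preset$freq_range[2])
        fw <- list()
        if (!identical(preset$freeze_frac, 0)) {
          frac <- stats::runif(1, preset$freeze_frac[1], preset$freeze_frac[2])
          nwin <- 3L
          slot <- duration_s / nwin
          wlen <- frac * duration_s / nwin
          for (j in seq_len(nwin)) {
            s0 <- (j - 1L) * slot + stats::runif(1, 0, slot - wlen)
            fw[[j]] <- list(start_s = s0, end_s = s0 + wlen,
                            tremor_hz = stats::runif(1, 4, 7),
                            tremor_amp = stats::runif(1, 0.3, 0.6))
          }
        }
        cfg <- gait_sim_config(
          gait_freq_hz = f0, duration_s = duration_s, fps = fps, view = view,
          noise_sd_px = preset$noise_sd_px, dropout_prob = preset$dropout_prob,
          freeze_windows = fw, amplitude_scale = preset$amplitude_scale,
          freq_jitter = preset$freq_jitter,
          seed = sample.int(.Machine$integer.max - 1L, 1L)
        )
        sim <- simulate_gait(cfg)
        out[[length(out) + 1L]] <- list(seq = sim$seq, truth = sim$truth,
                                        label = label,
                                        id = sprintf("%s_%02d", label, i))
      }
    }
    attr(out, "labels") <- vapply(out, `[[`, character(1), "label")
    out
  })
}
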