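# Fixture builders shared across test files. Everything is generated in
# code; no data files.

`%||%` <- function(a, b) if (is.null(a)) b else a

# a minimal valid 18-keypoint frame matrix set with legs at given endpoints
make_leg_seq <- function(rhip, rank, lhip, lank, n = 1L, fps = 100) {
  x <- matrix(0, n, 18); y <- matrix(0, n, 18); conf <- matrix(0.9, n, 18)
  set_kp <- function(kp, p) {
    x[, kp + 1L] <<- p[1]; y[, kp + 1L] <<- p[2]
  }
  set_kp(8L, rhip); set_kp(10L, rank); set_kp(11L, lhip); set_kp(13L, lank)
  keypoint_seq(x, y, conf, fps, "frontal", "fixture")
}

# pure-tone feature series
tone_series <- function(freq_hz, duration_s = 12, fps = 100, phase = 0,
                        kind = "LRdiff", view = "frontal") {
  t <- seq(0, duration_s, by = 1 / fps)
  feature_series(t, sin(2 * pi * freq_hz * t + phase), fps, kind, view = view)
}

# clean simulated sequence -> filtered feature series
sim_feature <- function(f0, view = "frontal", duration_s = 12, fps = 100,
                        seed = 1, ...) {
  sim <- simulate_gait(gait_sim_config(f0, duration_s = duration_s, fps = fps,
                                       view = view, seed = seed, ...))
  s <- resample_keypoints(clean_and_interpolate(sim$seq), 100)
  raw <- if (view == "frontal") compute_lrdiff(s) else compute_lrang(s)
  bandpass(raw)
}

# write a per-frame pose JSON file in the standard pose-estimator layout
write_pose_frame <- function(path, people_kps) {
  # people_kps: list of numeric vectors (flat x,y,conf triples)
  jsonlite::write_json(
    list(version = 1.3,
         people = lapply(people_kps, function(kp)
           list(pose_keypoints_2d = kp))),
    path, auto_unbox = TRUE, digits = NA)
  path
}

flat_kps <- function(x, y, conf) {
  as.vector(rbind(x, y, conf))
}

# brute-force DTW oracle: enumerate all monotone warping paths on short
# curves; returns min cost / (shortest path length among min-cost paths)
dtw_oracle <- function(a, b) {
  n <- length(a); m <- length(b)
  best <- list()
  # recursive enumeration from (1,1) to (n,m)
  rec <- function(i, j, cost, len) {
    cost <- cost + abs(a[i] - b[j]); len <- len + 1L
    if (i == n && j == m) {
      best[[length(best) + 1L]] <<- c(cost, len)
      return(invisible())
    }
    if (i < n && j < m) rec(i + 1L, j + 1L, cost, len)
    if (i < n) rec(i + 1L, j, cost, len)
    if (j < m) rec(i, j + 1L, cost, len)
  }
  rec(1L, 1L, 0, 0L)
  mat <- do.call(rbind, best)
  mc <- min(mat[, 1])
  ml <- min(mat[mat[, 1] <= mc + 1e-12, 2])
  mc / ml
}
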