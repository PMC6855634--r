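test_that("pose JSON frames are read in order and per frame", {
  dir <- withr::local_tempdir()
  for (i in 0:2) {
    kp <- flat_kps(rep(100 + i, 18), rep(200, 18), rep(0.9, 18))
    write_pose_frame(file.path(dir, sprintf("walk_%012d_keypoints.json", i)),
                     list(kp))
  }
  seq <- read_pose_json(list.files(dir, full.names = TRUE), fps = 25,
                        view = "frontal")
  expect_equal(n_frames(seq), 3L)
  expect_equal(seq$fps, 25)
  expect_equal(seq$x[, 1], c(100, 101, 102))
})

test_that("a frame with an empty people list becomes all-missing", {
  dir <- withr::local_tempdir()
  write_pose_frame(file.path(dir, "f_0.json"),
                   list(flat_kps(rep(1, 18), rep(2, 18), rep(0.8, 18))))
  write_pose_frame(file.path(dir, "f_1.json"), list())
  seq <- read_pose_json(list.files(dir, full.names = TRUE), fps = 25,
                        view = "frontal")
  expect_true(all(seq$conf[2, ] == 0))
  expect_true(all(seq$conf[1, ] == 0.8))
})

test_that("the highest-mean-confidence person is kept in multi-person frames", {
  dir <- withr::local_tempdir()
  good <- flat_kps(rep(10, 18), rep(20, 18), rep(0.9, 18))
  poor <- flat_kps(rep(99, 18), rep(99, 18), rep(0.4, 18))
  write_pose_frame(file.path(dir, "f_0.json"), list(poor, good))
  seq <- read_pose_json(file.path(dir, "f_0.json"), fps = 25, view = "frontal")
  expect_equal(unname(seq$x[1, ]), rep(10, 18))
  expect_equal(unname(seq$conf[1, ]), rep(0.9, 18))
})

test_that("malformed JSON and bad triple lists are hard errors naming the file", {
  dir <- withr::local_tempdir()
  bad <- file.path(dir, "broken_0.json")
  writeLines("{not json", bad)
  expect_error(read_pose_json(bad, fps = 25, view = "frontal"), "broken_0")
  trunc <- file.path(dir, "trunc_0.json")
  write_pose_frame(trunc, list(c(1, 2, 0.5, 7)))  # length 4: not triples
  expect_error(read_pose_json(trunc, fps = 25, view = "frontal"),
               "multiple of 3")
})

test_that("keypoint CSV round trip preserves a simulated sequence", {
  sim <- simulate_gait(gait_sim_config(1.0, duration_s = 2, fps = 25,
                                       noise_sd_px = 1, dropout_prob = 0.05,
                                       seed = 4))
  path <- withr::local_tempfile(fileext = ".csv")
  write_keypoint_csv(sim$seq, path)
  back <- read_keypoint_csv(path, fps = 25, view = "frontal")
  expect_equal(back$x, sim$seq$x)
  expect_equal(back$y, sim$seq$y)
  expect_equal(back$conf, sim$seq$conf)
})

test_that("CSV reader: missing pairs get confidence 0, row order is irrelevant, bad kp_index errors", {
  sim <- simulate_gait(gait_sim_config(1.0, duration_s = 1, fps = 25, seed = 4))
  path <- withr::local_tempfile(fileext = ".csv")
  write_keypoint_csv(sim$seq, path)
  df <- utils::read.csv(path)
  # drop left ankle (kp 13) of frame 5
  df2 <- df[!(df$frame == 5 & df$kp_index == 13), ]
  p2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df2, p2, row.names = FALSE)
  back <- read_keypoint_csv(p2, fps = 25, view = "frontal")
  expect_equal(back$conf[6, 14], 0)

  set.seed(1)
  df3 <- df[sample.int(nrow(df)), ]
  p3 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df3, p3, row.names = FALSE)
  shuffled <- read_keypoint_csv(p3, fps = 25, view = "frontal")
  expect_equal(shuffled$x, sim$seq$x)

  df$kp_index[1] <- 18L
  p4 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df, p4, row.names = FALSE)
  expect_error(read_keypoint_csv(p4, fps = 25, view = "frontal"), "kp_index")
})

test_that("interpolation fills short gaps linearly and leaves long gaps invalid", {
  n <- 50; fps <- 10
  x <- matrix(100, n, 18); y <- matrix(200, n, 18); conf <- matrix(0.8, n, 18)
  x[, 11] <- seq(10, 10 + n - 1)      # keypoint 10 moves linearly
  x[20, 11] <- 0; conf[20, 11] <- 0   # single missing frame (0.1 s)
  conf[30:45, 11] <- 0; x[30:45, 11] <- 0  # 1.6 s gap
  seq <- keypoint_seq(x, y, conf, fps, "frontal")
  out <- clean_and_interpolate(seq, max_gap_s = 0.5)
  expect_equal(out$x[20, 11], (out$x[19, 11] + out$x[21, 11]) / 2)
  expect_equal(out$conf[20, 11], 0.8)
  expect_true(all(out$conf[30:45, 11] == 0))
  # untouched channels identical
  expect_equal(out$x[, 1], seq$x[, 1])
})

test_that("interpolation never alters detected frames and no-gap input is identity", {
  sim <- simulate_gait(gait_sim_config(1.0, duration_s = 3, fps = 25,
                                       noise_sd_px = 1, dropout_prob = 0.1,
                                       seed = 9))
  out <- clean_and_interpolate(sim$seq, 0.2)
  det <- sim$seq$conf > 0
  expect_equal(out$x[det], sim$seq$x[det])
  expect_equal(out$y[det], sim$seq$y[det])

  clean <- simulate_gait(gait_sim_config(1.0, duration_s = 2, fps = 25, seed = 2))$seq
  expect_equal(clean_and_interpolate(clean, 0.2), clean)
})

test_that("a never-detected keypoint warns and stays invalid", {
  n <- 20
  x <- matrix(1, n, 18); y <- matrix(1, n, 18); conf <- matrix(0.9, n, 18)
  conf[, 5] <- 0; x[, 5] <- 0; y[, 5] <- 0
  seq <- keypoint_seq(x, y, conf, 25, "frontal")
  expect_warning(out <- clean_and_interpolate(seq), "never detected")
  expect_true(all(out$conf[, 5] == 0))
})

test_that("resampling to own fps is the identity and preserves linear ramps", {
  sim <- simulate_gait(gait_sim_config(1.0, duration_s = 2, fps = 25,
                                       noise_sd_px = 0.5, seed = 3))$seq
  same <- resample_keypoints(sim, 25)
  expect_equal(same$x, sim$x, tolerance = 1e-9)
  expect_equal(same$conf, sim$conf, tolerance = 1e-9)

  n <- 76  # 3.0 s at 25 fps
  x <- matrix(seq(0, 3, length.out = n), n, 18)
  y <- x + 5
  seq <- keypoint_seq(x, y, matrix(0.9, n, 18), 25, "frontal")
  up <- resample_keypoints(seq, 100)
  expect_equal(n_frames(up), 301L)
  expect_equal(up$x[, 1], seq(0, 3, length.out = 301), tolerance = 1e-9)
})

test_that("resampling refuses to downsample and does not bridge dropouts", {
  sim <- simulate_gait(gait_sim_config(1.0, duration_s = 2, fps = 50, seed = 3))$seq
  expect_error(resample_keypoints(sim, 25), "downsampling")

  n <- 26
  x <- matrix(1, n, 18); conf <- matrix(0.9, n, 18)
  conf[10:12, 3] <- 0
  seq <- keypoint_seq(x, x, conf, 25, "frontal")
  up <- resample_keypoints(seq, 100)
  t_new <- (0:(n_frames(up) - 1)) / 100
  inside <- t_new > 8 / 25 & t_new < 12 / 25  # strictly within the gap
  expect_true(all(up$conf[inside, 3] == 0))
  ok <- t_new < 8 / 25 | t_new > 12 / 25
  expect_true(all(up$conf[ok, 3] > 0))
})
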