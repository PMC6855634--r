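ref_from_sim <- function(f0 = 1.0, seed = 42, window_s = 2.0, shift_s = 0.05,
                         duration_s = 10, ...) {
  build_reference(st_acf(sim_feature(f0, seed = seed, duration_s = duration_s, ...),
                         window_s, shift_s))
}

test_that("the reference gate accepts periodic gait and rejects noise", {
  ref <- ref_from_sim()
  expect_s3_class(ref, "acf_reference")
  expect_equal(ref$aggregate_curve[1], 1, tolerance = 1e-9)
  expect_true(all(abs(ref$curves[1, ] - 1) < 1e-9))

  t <- seq(0, 8, by = 0.01)
  set.seed(13)
  noise <- feature_series(t, rnorm(length(t)), 100, "LRdiff", view = "frontal")
  expect_error(build_reference(st_acf(noise, 2.0, shift_s = 0.05)),
               "quality gate")
})

test_that("DTW distance is zero for identical curves and matches a brute-force oracle", {
  ref <- ref_from_sim()
  # query = the reference's own aggregate curve in every window
  q <- ref$curves
  a <- structure(list(acf = cbind(ref$aggregate_curve),
                      lags_s = ref$lags_s, t_centers = 0,
                      window_s = ref$window_s, shift_s = 0.05, fps = ref$fps,
                      n_eff = nrow(q), window_valid = TRUE,
                      kind = "LRdiff", view = "frontal"), class = "stacf")
  expect_identical(dtw_distance_series(a, ref), 0)

  # brute-force oracle on short random curves
  set.seed(77)
  for (i in 1:20) {
    x <- round(rnorm(sample(3:6, 1)), 2)
    y <- round(rnorm(sample(3:6, 1)), 2)
    expect_equal(gaitacf:::dtw_norm_cpp(x, y), dtw_oracle(x, y), tolerance = 1e-12)
  }
})

test_that("DTW of a one-step shift is small and bounded by the Euclidean distance", {
  ref <- ref_from_sim()
  cur <- ref$aggregate_curve
  shifted <- c(cur[-1], cur[length(cur)])
  d <- gaitacf:::dtw_norm_cpp(shifted, cur)
  expect_gt(d, 0)
  # normalized alignment cost cannot exceed the rigid (unwarped) distance
  expect_lte(d, sqrt(sum((shifted - cur)^2)))
  expect_lt(d, 0.01)
})

test_that("DTW of a constant-zero curve equals the mean absolute reference value", {
  set.seed(5)
  for (n in c(4, 9, 30)) {
    refc <- rnorm(n)
    expect_equal(gaitacf:::dtw_norm_cpp(rep(0, n), refc), mean(abs(refc)),
                 tolerance = 1e-12)
  }
})

test_that("kNN scores match an exhaustive oracle exactly for k in {1,3,5}", {
  set.seed(123)
  L <- 40; n_ref <- 12; n_query <- 20
  R <- matrix(rnorm(L * n_ref), L, n_ref)
  Q <- matrix(rnorm(L * n_query), L, n_query)
  ref <- structure(list(curves = R, aggregate_curve = rowMeans(R),
                        lags_s = (0:(L - 1)) / 100, window_s = (L - 1) / 100,
                        fps = 100, source_id = "oracle"), class = "acf_reference")
  a <- structure(list(acf = Q, lags_s = ref$lags_s,
                      t_centers = seq_len(n_query), window_s = ref$window_s,
                      shift_s = 1, fps = 100, n_eff = rep(L, n_query),
                      window_valid = rep(TRUE, n_query),
                      kind = "LRdiff", view = "frontal"), class = "stacf")
  for (k in c(1, 3, 5)) {
    got <- knn_anomaly_series(a, ref, k = k)
    want <- apply(Q, 2, function(q) {
      d <- sort(sqrt(colSums((R - q)^2)))
      mean(d[1:k])
    })
    expect_equal(got, want, tolerance = 1e-12)
  }
  # boundary: k = reference size -> mean distance to all curves
  all_k <- knn_anomaly_series(a, ref, k = n_ref)
  want_all <- apply(Q, 2, function(q) mean(sqrt(colSums((R - q)^2))))
  expect_equal(all_k, want_all, tolerance = 1e-12)
  expect_error(knn_anomaly_series(a, ref, k = n_ref + 1), "at least k")
})

test_that("a query equal to a reference curve has kNN score 0 at k = 1", {
  ref <- ref_from_sim()
  a <- structure(list(acf = ref$curves[, 3, drop = FALSE],
                      lags_s = ref$lags_s, t_centers = 0,
                      window_s = ref$window_s, shift_s = 0.05, fps = ref$fps,
                      n_eff = nrow(ref$curves), window_valid = TRUE,
                      kind = "LRdiff", view = "frontal"), class = "stacf")
  expect_equal(knn_anomaly_series(a, ref, k = 1), 0, tolerance = 1e-9)
})

test_that("injected freezing never decreases the median DTW or kNN distance", {
  ref <- ref_from_sim()
  knn_lib <- merge_references(list(
    ref, ref_from_sim(0.9, seed = 43), ref_from_sim(1.1, seed = 44)))
  worse_dtw <- 0; worse_knn <- 0; n_seeds <- 20
  for (seed in seq_len(n_seeds)) {
    base_cfg <- list(duration_s = 8, fps = 100, noise_sd_px = 1,
                     dropout_prob = 0, seed = 5000 + seed)
    clean <- do.call(gait_sim_config, c(list(gait_freq_hz = 1.0), base_cfg))
    frozen <- do.call(gait_sim_config, c(
      list(gait_freq_hz = 1.0,
           freeze_windows = list(list(start_s = 2, end_s = 5.5,
                                      tremor_hz = 5, tremor_amp = 0.5))),
      base_cfg))
    med <- lapply(list(clean, frozen), function(cfg) {
      s <- bandpass(compute_lrdiff(simulate_gait(cfg)$seq))
      d <- distance_series(st_acf(s, 2.0, shift_s = 0.05), ref, knn_ref = knn_lib)
      c(dtw = stats::median(d$dtw, na.rm = TRUE),
        knn = stats::median(d$knn, na.rm = TRUE))
    })
    worse_dtw <- worse_dtw + (med[[2]]["dtw"] >= med[[1]]["dtw"])
    worse_knn <- worse_knn + (med[[2]]["knn"] >= med[[1]]["knn"])
  }
  expect_equal(unname(worse_dtw), n_seeds)
  expect_equal(unname(worse_knn), n_seeds)
})

test_that("group comparison: identical groups give AUC 0.5; disjoint groups separate perfectly", {
  mk_ds <- function(dtw, knn) structure(
    list(t_centers = seq_along(dtw), dtw = dtw, knn = knn,
         reference_id = "r", k = 1L, window_s = 2), class = "distance_series")
  same <- mk_ds(c(1, 2, 3, 4), c(1, 2, 3, 4))
  cmp <- summarize_and_compare(list(a = same, b = same))
  expect_equal(cmp$dtw$pairwise_auc$auc, 0.5)
  expect_equal(cmp$knn$pairwise_auc$auc, 0.5)

  lo <- mk_ds(c(0, 0, 0), c(0, 0, 0))
  hi <- mk_ds(c(1, 1, 1), c(1, 1, 1))
  cmp2 <- suppressWarnings(summarize_and_compare(list(ctrl = lo, severe = hi)))
  expect_equal(cmp2$dtw$pairwise_auc$auc, 1.0)
  expect_lt(cmp2$dtw$anova$p, 0.05)
})

test_that("AUC equals the Mann-Whitney U identity on random data", {
  set.seed(9)
  mk_ds <- function(v) structure(
    list(t_centers = seq_along(v), dtw = v, knn = v,
         reference_id = "r", k = 1L, window_s = 2), class = "distance_series")
  x <- rnorm(25); y <- rnorm(30, mean = 0.4)
  cmp <- summarize_and_compare(list(g1 = mk_ds(x), g2 = mk_ds(y)))
  u <- sum(outer(y, x, ">")) + 0.5 * sum(outer(y, x, "=="))
  expect_equal(cmp$dtw$pairwise_auc$auc, u / (length(x) * length(y)),
               tolerance = 1e-12)
})

test_that("reference serialization round-trips curves and metadata", {
  ref <- ref_from_sim(duration_s = 6)
  path <- withr::local_tempfile(fileext = ".csv")
  write_reference(ref, path)
  back <- read_reference(path)
  expect_equal(back$curves, ref$curves, tolerance = 1e-6)
  expect_equal(back$window_s, ref$window_s)
  expect_equal(back$fps, ref$fps)
  expect_equal(back$cadence$cadence_steps_per_min,
               ref$cadence$cadence_steps_per_min, tolerance = 1e-9)
})
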