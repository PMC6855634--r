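#' Pipeline configuration
#'
#' Bundles every tunable parameter of the end-to-end pipeline. All defaults
#' are the reference settings of the method: resampling to 100 fps,
#' 0.1-7 Hz feature band, 2 s analysis windows for normal gait (3 s for the
#' pathological preset), 0.01 s window shift, lag search band mirroring the
#' feature band, k = 5 reference neighbours.
#'
#' @param input path to a keypoint CSV ([read_keypoint_csv()] dialect), or
#'   NULL to simulate input via `simulate`.
#' @param simulate a [gait_sim_config()] used when `input` is NULL.
#' @param view camera view of the input.
#' @param fps frame rate of the input CSV (ignored when simulating).
#' @param fps_target working frame rate after resampling (default 100).
#' @param band band-pass edges in Hz (default `c(0.1, 7)`).
#' @param preset `"normal"` (2 s windows) or `"pathological"` (3 s).
#' @param window_s explicit window length; overrides `preset`.
#' @param shift_s window shift in seconds (default 0.01).
#' @param lag_min_s,lag_max_s lag search band (defaults 1/7 and 10 s).
#' @param max_gap_s longest keypoint dropout bridged by interpolation.
#' @param conf_floor keypoint confidence floor.
#' @param k neighbours for the kNN anomaly score.
#' @param reference path to a serialized ACF reference
#'   ([write_reference()]); enables the periodicity stage.
#' @param out_dir directory for stage artifacts; NULL writes nothing.
#' @param seed seed forwarded to simulation when `simulate` lacks one.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, simulate = NULL,
                            view = c("frontal", "lateral"), fps = 100,
                            fps_target = 100, band = c(0.1, 7),
                            preset = c("normal", "pathological"),
                            window_s = NULL, shift_s = 0.01,
                            lag_min_s = 1 / 7, lag_max_s = 10,
                            max_gap_s = 0.2, conf_floor = 0, k = 5L,
                            reference = NULL, out_dir = NULL, seed = NULL) {
  view <- match.arg(view)
  preset <- match.arg(preset)
  if (is.null(window_s))
    window_s <- if (preset == "normal") 2.0 else 3.0
  structure(list(
    input = input, simulate = simulate, view = view, fps = fps,
    fps_target = fps_target, band = band, preset = preset,
    window_s = window_s, shift_s = shift_s,
    lag_min_s = lag_min_s, lag_max_s = lag_max_s,
    max_gap_s = max_gap_s, conf_floor = conf_floor, k = as.integer(k),
    reference = reference, out_dir = out_dir, seed = seed
  ), class = "pipeline_config")
}

config_as_list <- function(config) {
  out <- unclass(config)
  out$simulate <- if (is.null(out$simulate)) NULL else unclass(out$simulate)
  out
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full gait-quantification pipeline
#'
#' Chains the stages: read (or simulate) keypoints, clean and resample,
#' compute the view-appropriate gait feature (LRdiff for frontal, LRang for
#' lateral), band-pass filter, short-time ACF, cadence estimation, and -
#' when a reference is supplied - DTW/kNN periodicity scoring. Every
#' artifact and the full effective configuration are written to
#' `config$out_dir` when set.
#'
#' @param config a [pipeline_config()].
#' @return List with `seq`, `feature`, `stacf`, `cadence` (NULL if no
#'   window was significant; `cadence_error` then carries the message),
#'   `distances` (NULL without a reference), and `config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  seq <- run_stage("input", {
    if (!is.null(config$input)) {
      if (!file.exists(config$input))
        stop("input file not found: ", config$input)
      read_keypoint_csv(config$input, fps = config$fps, view = config$view)
    } else if (!is.null(config$simulate)) {
      sim <- config$simulate
      if (!is.null(config$seed)) sim$seed <- as.integer(config$seed)
      simulate_gait(sim)$seq
    } else stop("config needs either 'input' or 'simulate'")
  })

  seq <- run_stage("clean", clean_and_interpolate(seq, config$max_gap_s))
  seq <- run_stage("resample", resample_keypoints(seq, config$fps_target))

  feature <- run_stage("features", {
    raw <- if (config$view == "frontal") compute_lrdiff(seq, config$conf_floor)
           else compute_lrang(seq, config$conf_floor)
    bandpass(raw, config$band[1], config$band[2])
  })

  stacf <- run_stage("stacf", st_acf(feature, config$window_s, config$shift_s))

  cadence <- NULL; cadence_error <- NULL
  cad_try <- tryCatch(
    estimate_cadence(stacf, view = config$view,
                     lag_min_s = config$lag_min_s, lag_max_s = config$lag_max_s),
    gaitacf_no_significant_window = function(e) e)
  if (inherits(cad_try, "cadence_estimate")) cadence <- cad_try
  else cadence_error <- conditionMessage(cad_try)

  distances <- NULL
  if (!is.null(config$reference)) {
    distances <- run_stage("periodicity", {
      ref <- read_reference(config$reference)
      distance_series(stacf, ref, k = config$k)
    })
  }

  if (!is.null(config$out_dir)) {
    run_stage("write", {
      dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
      write_feature_csv(feature, file.path(config$out_dir, "feature.csv"))
      write_stacf_csv(stacf, file.path(config$out_dir, "stacf.csv"))
      cad_json <- if (!is.null(cadence)) {
        list(cadence_steps_per_min = cadence$cadence_steps_per_min,
             representative_freq_hz = cadence$representative_freq_hz,
             representative_lag_s = cadence$representative_lag_s,
             view = cadence$view,
             n_windows = cadence$n_windows,
             n_significant = cadence$n_significant,
             per_window = cadence$per_window)
      } else list(error = cadence_error)
      jsonlite::write_json(cad_json, file.path(config$out_dir, "cadence.json"),
                           auto_unbox = TRUE, digits = NA, dataframe = "columns")
      if (!is.null(distances))
        utils::write.csv(
          data.frame(t_center = distances$t_centers,
                     dtw = distances$dtw, knn = distances$knn),
          file.path(config$out_dir, "distance.csv"), row.names = FALSE)
      jsonlite::write_json(
        list(config = config_as_list(config),
             cadence_steps_per_min =
               if (is.null(cadence)) NA else cadence$cadence_steps_per_min,
             cadence_error = cadence_error,
             median_dtw = if (is.null(distances)) NA
                          else stats::median(distances$dtw, na.rm = TRUE),
             median_knn = if (is.null(distances)) NA
                          else stats::median(distances$knn, na.rm = TRUE)),
        file.path(config$out_dir, "summary.json"),
        auto_unbox = TRUE, digits = NA, null = "null")
    })
  }

  invisible(list(seq = seq, feature = feature, stacf = stacf,
                 cadence = cadence, cadence_error = cadence_error,
                 distances = distances, config = config))
}
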