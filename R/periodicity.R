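#' Build a normal-gait ACF reference
#'
#' Stores the per-window autocorrelation curves of a normal-gait ST-ACF
#' matrix, together with their element-wise mean, for use as the reference
#' that pathological sequences are scored against. The candidate sequence
#' must pass a quality gate: [estimate_cadence()] must succeed and at least
#' `min_significant_frac` of its valid windows must carry a significant
#' autocorrelation peak, so that only convincingly periodic gait can serve
#' as "normal".
#'
#' @param stacf an [st_acf()] matrix from a normal-gait sequence.
#' @param view view used for the gate's cadence estimate (default: as
#'   recorded in `stacf`).
#' @param min_significant_frac minimum fraction of valid windows with a
#'   significant peak (default 0.8).
#' @return An object of class `acf_reference`: `curves` (lags x windows
#'   matrix of valid-window curves), `aggregate_curve`, `lags_s`,
#'   `window_s`, `fps`, `source_id`, `cadence` (the gate's estimate).
#' @export
build_reference <- function(stacf, view = stacf$view, min_significant_frac = 0.8) {
  est <- tryCatch(estimate_cadence(stacf, view = view),
                  gaitacf_no_significant_window = function(e)
                    stop("reference quality gate failed: ", conditionMessage(e),
                         call. = FALSE))
  frac <- est$n_significant / max(est$n_valid, 1L)
  if (frac < min_significant_frac)
    stop(sprintf(paste0("reference quality gate failed: only %.0f%% of valid ",
                        "windows have a significant peak (need >= %.0f%%)"),
                 100 * frac, 100 * min_significant_frac), call. = FALSE)
  curves <- stacf$acf[, stacf$window_valid, drop = FALSE]
  structure(list(
    curves = curves,
    aggregate_curve = rowMeans(curves),
    lags_s = stacf$lags_s, window_s = stacf$window_s, fps = stacf$fps,
    source_id = attr(stacf, "source_id") %||% "reference",
    cadence = est
  ), class = "acf_reference")
}

#' @export
print.acf_reference <- function(x, ...) {
  cat(sprintf("<acf_reference> %d curves of %d lags (window %g s), source = %s\n",
              ncol(x$curves), nrow(x$curves), x$window_s, x$source_id))
  cat(sprintf("  reference cadence: %.1f steps/min\n",
              x$cadence$cadence_steps_per_min))
  invisible(x)
}

#' Per-window DTW distance from a normal-gait ACF reference
#'
#' For each valid window of the query ST-ACF matrix, the dynamic-time-
#' warping alignment cost between that window's autocorrelation curve
#' (a sequence over lags) and the reference, using absolute-difference
#' local cost, the symmetric step set, and normalization by warping-path
#' length so that distances are comparable between different window
#' lengths (e.g. 2 s references scoring 3 s pathological windows). DTW
#' tolerates both the length mismatch and shifts of the peak lags, which is
#' what lets one reference serve queries whose period differs.
#'
#' The distance is 0 between identical curves and grows as the query's
#' periodic structure departs from normal gait.
#'
#' @param stacf query [st_acf()] matrix.
#' @param ref an [build_reference()] object (same lag step as the query).
#' @param mode `"aggregate"` (default) compares against the reference's
#'   mean curve; `"min"` takes, per query window, the minimum distance over
#'   all reference curves.
#' @return Numeric vector, one value per query window (NA for invalid
#'   windows).
#' @export
dtw_distance_series <- function(stacf, ref, mode = c("aggregate", "min")) {
  mode <- match.arg(mode)
  step_q <- 1 / stacf$fps; step_r <- 1 / ref$fps
  if (abs(step_q - step_r) > 1e-9)
    stop("query and reference lag steps differ")
  W <- length(stacf$t_centers)
  out <- rep(NA_real_, W)
  for (w in seq_len(W)) {
    if (!stacf$window_valid[w]) next
    q <- stacf$acf[, w]
    out[w] <- if (mode == "aggregate") {
      dtw_norm_cpp(q, ref$aggregate_curve)
    } else {
      min(apply(ref$curves, 2L, function(rc) dtw_norm_cpp(q, rc)))
    }
  }
  out
}

#' Per-window kNN anomaly score from a normal-gait ACF reference
#'
#' For each valid query window, the mean Euclidean distance from its
#' autocorrelation vector to its `k` nearest reference curves. Query and
#' reference curves are truncated to their common lag range first, since
#' the metric needs a fixed dimension. Large scores flag windows whose
#' periodic structure is atypical of the reference gait.
#'
#' @inheritParams dtw_distance_series
#' @param k number of nearest reference curves to average over (default 5).
#' @return Numeric vector, one value per query window (NA for invalid
#'   windows).
#' @export
knn_anomaly_series <- function(stacf, ref, k = 5L) {
  if (abs(1 / stacf$fps - 1 / ref$fps) > 1e-9)
    stop("query and reference lag steps differ")
  k <- as.integer(k)
  nref <- ncol(ref$curves)
  if (nref < k)
    stop(sprintf("reference has %d curves; need at least k = %d", nref, k))
  L <- min(nrow(stacf$acf), nrow(ref$curves))
  R <- ref$curves[1:L, , drop = FALSE]
  W <- length(stacf$t_centers)
  out <- rep(NA_real_, W)
  rn2 <- colSums(R^2)
  for (w in seq_len(W)) {
    if (!stacf$window_valid[w]) next
    q <- stacf$acf[1:L, w]
    d2 <- pmax(sum(q^2) + rn2 - 2 * drop(crossprod(R, q)), 0)
    out[w] <- mean(sqrt(sort(d2, partial = k)[1:k]))
  }
  out
}

#' Pool several ACF references into one curve library
#'
#' Concatenates the per-window curves of references built from different
#' normal-gait sequences (all on the same lag grid). The pooled library is
#' what the kNN anomaly score should search: Euclidean distance on raw ACF
#' vectors is cadence-sensitive, so a library spanning the normal cadence
#' range is needed for "normal" queries of any cadence to find close
#' neighbours. The pooled aggregate curve mixes cadences and is therefore
#' a poor DTW target; keep a single-sequence reference for DTW.
#'
#' @param refs list of [build_reference()] objects on identical lag grids.
#' @return An `acf_reference` whose `curves` pool all inputs.
#' @export
merge_references <- function(refs) {
  stopifnot(length(refs) >= 1L,
            all(vapply(refs, inherits, logical(1), "acf_reference")))
  L <- vapply(refs, function(r) nrow(r$curves), integer(1))
  if (length(unique(L)) != 1L || length(unique(vapply(refs, `[[`, numeric(1), "fps"))) != 1L)
    stop("references must share one lag grid")
  curves <- do.call(cbind, lapply(refs, `[[`, "curves"))
  out <- refs[[1L]]
  out$curves <- curves
  out$aggregate_curve <- rowMeans(curves)
  out$source_id <- paste0("pool(", paste(vapply(refs, `[[`, character(1), "source_id"),
                                         collapse = ","), ")")
  out$cadence <- NULL
  out
}

#' Bundle DTW and kNN distance series for one sequence
#'
#' @inheritParams knn_anomaly_series
#' @param mode passed to [dtw_distance_series()].
#' @param knn_ref reference searched by the kNN score; defaults to `ref`.
#'   Pass a pooled library ([merge_references()]) here when query cadences
#'   span the normal range.
#' @return An object of class `distance_series`: `t_centers`, `dtw`, `knn`,
#'   `reference_id`, `k`, `window_s`.
#' @export
distance_series <- function(stacf, ref, k = 5L, mode = "aggregate",
                            knn_ref = ref) {
  structure(list(
    t_centers = stacf$t_centers,
    dtw = dtw_distance_series(stacf, ref, mode = mode),
    knn = knn_anomaly_series(stacf, knn_ref, k = k),
    reference_id = ref$source_id, k = as.integer(k),
    window_s = stacf$window_s
  ), class = "distance_series")
}

#' @export
print.distance_series <- function(x, ...) {
  ok <- is.finite(x$dtw)
  cat(sprintf("<distance_series> %d windows (%d valid), reference = %s, k = %d\n",
              length(x$t_centers), sum(ok), x$reference_id, x$k))
  cat(sprintf("  median DTW %.4f, median kNN %.4f\n",
              stats::median(x$dtw, na.rm = TRUE), stats::median(x$knn, na.rm = TRUE)))
  invisible(x)
}

#' @export
plot.distance_series <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$t_centers, x$dtw, type = "l", xlab = "window center (s)",
                 ylab = "DTW distance", ...)
  graphics::plot(x$t_centers, x$knn, type = "l", xlab = "window center (s)",
                 ylab = "kNN anomaly", ...)
  invisible(x)
}

pool_distance_values <- function(ds_list, metric) {
  unlist(lapply(ds_list, function(d) {
    v <- d[[metric]]
    v[is.finite(v)]
  }), use.names = FALSE)
}

#' Compare distance distributions across groups
#'
#' Pools the per-window DTW and kNN values of each group, runs a one-way
#' ANOVA of value on group per metric, and computes pairwise ROC AUC with
#' the window values as scores (oriented so that the later-listed - "more
#' affected" - group scores higher; an AUC near 1 means that group's
#' windows sit consistently farther from the normal-gait reference).
#'
#' @param groups named list; each element is a [distance_series()] or a
#'   list of them (one per sequence in the group). Order groups from least
#'   to most affected.
#' @return An object of class `distance_comparison`: for each metric, the
#'   per-group n/median/IQR, the ANOVA F and p, and a pairwise AUC table.
#' @export
summarize_and_compare <- function(groups) {
  if (is.null(names(groups)) || any(names(groups) == ""))
    stop("groups must be a named list")
  as_list <- lapply(groups, function(g)
    if (inherits(g, "distance_series")) list(g) else g)
  out <- list()
  for (metric in c("dtw", "knn")) {
    vals <- lapply(as_list, pool_distance_values, metric = metric)
    empty <- vapply(vals, function(v) length(v) == 0L, logical(1))
    if (any(empty)) {
      warning("group(s) with zero valid windows excluded: ",
              paste(names(vals)[empty], collapse = ", "))
      vals <- vals[!empty]
    }
    if (length(vals) < 2L)
      stop("need at least 2 non-empty groups to compare")
    if (any(vapply(vals, length, integer(1)) < 2L))
      stop("each group needs at least 2 pooled window values")
    df <- data.frame(
      value = unlist(vals, use.names = FALSE),
      group = factor(rep(names(vals), vapply(vals, length, integer(1))),
                     levels = names(vals))
    )
    an <- stats::anova(stats::lm(value ~ group, data = df))
    gnames <- names(vals)
    pairs <- utils::combn(gnames, 2L)
    auc <- apply(pairs, 2L, function(p) {
      r <- pROC::roc(response = factor(rep(p, c(length(vals[[p[1]]]), length(vals[[p[2]]]))),
                                       levels = p),
                     predictor = c(vals[[p[1]]], vals[[p[2]]]),
                     levels = p, direction = "<", quiet = TRUE)
      as.numeric(pROC::auc(r))
    })
    out[[metric]] <- list(
      group_stats = data.frame(
        group = gnames,
        n = vapply(vals, length, integer(1)),
        median = vapply(vals, stats::median, numeric(1)),
        iqr = vapply(vals, stats::IQR, numeric(1)),
        row.names = NULL
      ),
      anova = list(F = an$`F value`[1], p = an$`Pr(>F)`[1],
                   df = unname(an$Df)),
      pairwise_auc = data.frame(
        group1 = pairs[1, ], group2 = pairs[2, ], auc = auc,
        row.names = NULL
      )
    )
  }
  structure(out, class = "distance_comparison")
}

#' @export
print.distance_comparison <- function(x, ...) {
  for (metric in names(x)) {
    m <- x[[metric]]
    cat(sprintf("== %s ==\n", toupper(metric)))
    print(m$group_stats, row.names = FALSE)
    cat(sprintf("one-way ANOVA: F(%d, %d) = %.2f, p = %.3g\n",
                m$anova$df[1], m$anova$df[2], m$anova$F, m$anova$p))
    print(m$pairwise_auc, row.names = FALSE)
  }
  invisible(x)
}

#' Serialize / load an ACF reference
#'
#' Curves go to a CSV (rows = windows, columns = lags); lag step, window
#' length and source id go to a small JSON sidecar at `paste0(path, ".json")`.
#'
#' @param ref an [build_reference()] object.
#' @param path CSV path for the curves.
#' @export
write_reference <- function(ref, path) {
  m <- t(ref$curves)
  colnames(m) <- sprintf("lag_%.4f", ref$lags_s)
  utils::write.csv(as.data.frame(m), path, row.names = FALSE)
  jsonlite::write_json(
    list(lag_step_s = 1 / ref$fps, window_s = ref$window_s,
         source_id = ref$source_id,
         cadence_steps_per_min = ref$cadence$cadence_steps_per_min),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_reference
#' @export
read_reference <- function(path) {
  meta <- jsonlite::fromJSON(paste0(path, ".json"))
  curves <- t(as.matrix(utils::read.csv(path)))
  dimnames(curves) <- NULL
  structure(list(
    curves = curves,
    aggregate_curve = rowMeans(curves),
    lags_s = (0:(nrow(curves) - 1L)) * meta$lag_step_s,
    window_s = meta$window_s, fps = 1 / meta$lag_step_s,
    source_id = meta$source_id,
    cadence = list(cadence_steps_per_min = meta$cadence_steps_per_min)
  ), class = "acf_reference")
}
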