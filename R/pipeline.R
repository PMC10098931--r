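#' Pipeline configuration
#'
#' Bundles every threshold the pose-to-label pipeline uses. Defaults are
#' the recommended operating point: third-order Butterworth at 14 Hz run
#' zero-phase, 60-frame valley merge, 150-frame phase-floor flag, 50 px
#' median step rule, five CV folds with a 10% holdout. The EM smoother is
#' off by default (the Butterworth stage already suppresses jitter; EM is
#' available when the noise level is unknown a priori).
#'
#' @param filter_order,filter_cutoff Butterworth design (order, Hz).
#' @param zero_phase forward-backward filtering (recommended: keeps
#'   valley frames unshifted).
#' @param use_em also run the EM smoother before the Butterworth stage.
#' @param merge_gap minimum frames between distinct valleys.
#' @param phase_floor frames under which a segment is flagged incomplete.
#' @param step_rule px below the median step length at which a segment is
#'   discarded.
#' @param prominence valley prominence (`NULL`: 10% of range).
#' @param conf_floor confidence below which an observation is missing.
#' @param gap_window least-squares gap-fill half-window (frames).
#' @param granularity `"sequence"` (one feature vector per sequence over
#'   the retained-cycle span) or `"cycle"` (one per step segment).
#' @param folds,holdout cross-validation design.
#' @param fuse_knn average SVM scores with KNN vote fractions.
#' @param kernel,cost SVM settings.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(filter_order = 3, filter_cutoff = 14,
                            zero_phase = TRUE, use_em = FALSE,
                            merge_gap = 60, phase_floor = 150,
                            step_rule = 50, prominence = NULL,
                            conf_floor = 0, gap_window = 5,
                            granularity = c("sequence", "cycle"),
                            folds = 5, holdout = 0.10, fuse_knn = FALSE,
                            kernel = "radial", cost = 1) {
  granularity <- match.arg(granularity)
  stopifnot(filter_order >= 1, filter_cutoff > 0, merge_gap > 0,
            phase_floor > 0, step_rule > 0)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognized keys match the arguments of [pipeline_config()]; unknown
#' keys are an error so typos do not silently fall back to defaults.
#'
#' @param path YAML file.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(pipeline_config, vals)
}

# vertical coordinate channel: world z for 3D data; negated image y for
# 2D data so that "up" is positive either way
vertical_track <- function(seq, keypoint) {
  if (seq$dims == 3) keypoint_track(seq, keypoint, "z")
  else -keypoint_track(seq, keypoint, "y")
}

# linear interpolation over any NAs left after gap filling, constant
# extrapolation at the ends; errors only if a channel is entirely missing
interp_na <- function(x) {
  if (!anyNA(x)) return(x)
  ok <- which(!is.na(x))
  if (length(ok) < 2) stop("data error: channel almost entirely missing")
  stats::approx(ok, x[ok], xout = seq_along(x), rule = 2)$y
}

#' Extract the classification channels of a sequence
#'
#' Gap-fills the sequence, computes the eight base channels -- left/right
#' ankle forward coordinate, left/right pole-tip vertical coordinate,
#' left/right elbow and knee angle series -- smooths each with the
#' configured zero-phase Butterworth design, and appends two bilateral
#' difference channels (left-minus-right elbow angle and ankle forward
#' coordinate). The difference channels carry the interlimb phase
#' relation that distinguishes bilateral from alternating techniques,
#' which no per-channel statistic of the base channels can see.
#'
#' @param seq a [pose_sequence()] with the default key-point taxonomy.
#' @param config a [pipeline_config()].
#' @param diff_channels append the bilateral difference channels.
#' @param .filled internal: a pre-gap-filled copy of `seq`.
#' @return a [channel_set()] spanning the full sequence.
#' @export
extract_channels <- function(seq, config = pipeline_config(),
                             diff_channels = TRUE, .filled = NULL) {
  stopifnot(inherits(seq, "pose_sequence"))
  filled <- if (is.null(.filled)) fill_gaps(seq, window = config$gap_window) else .filled
  spec <- filter_spec(config$filter_order, config$filter_cutoff,
                      fs = seq$frame_rate, zero_phase = config$zero_phase)
  smooth1 <- function(x) {
    x <- interp_na(x)
    if (config$use_em && length(x) >= 10 && stats::var(x) > 0) {
      x <- em_smooth(x)$smoothed
    }
    butterworth_filter(x, spec)
  }
  ang <- angle_series(filled)
  ch <- list(
    left_ankle_x = smooth1(keypoint_track(filled, "left_ankle", "x")),
    right_ankle_x = smooth1(keypoint_track(filled, "right_ankle", "x")),
    left_pole_z = smooth1(vertical_track(filled, "left_pole_tip")),
    right_pole_z = smooth1(vertical_track(filled, "right_pole_tip")),
    left_elbow_ang = smooth1(ang$left_elbow),
    right_elbow_ang = smooth1(ang$right_elbow),
    left_knee_ang = smooth1(ang$left_knee),
    right_knee_ang = smooth1(ang$right_knee))
  if (diff_channels) {
    ch$elbow_lr_diff <- ch$left_elbow_ang - ch$right_elbow_ang
    ch$ankle_lr_diff <- ch$left_ankle_x - ch$right_ankle_x
  }
  channel_set(ch, seq$frame_rate)
}

#' Segment a sequence into motion cycles
#'
#' Runs the valley machinery on the detrended, smoothed left-ankle
#' forward coordinate (foot landings) and returns the merged valleys and
#' the filtered step segments.
#'
#' @param seq a [pose_sequence()].
#' @param config a [pipeline_config()].
#' @param .filled internal: a pre-gap-filled copy of `seq`.
#' @return as [segment_cycles()].
#' @export
segment_sequence <- function(seq, config = pipeline_config(), .filled = NULL) {
  filled <- if (is.null(.filled)) fill_gaps(seq, window = config$gap_window) else .filled
  track <- interp_na(keypoint_track(filled, "left_ankle", "x"))
  spec <- filter_spec(config$filter_order, config$filter_cutoff,
                      fs = seq$frame_rate, zero_phase = config$zero_phase)
  segment_cycles(track, seq$frame_rate, spec = spec, detrend = TRUE,
                 prominence = config$prominence,
                 min_gap = config$merge_gap,
                 median_margin = config$step_rule,
                 min_phase_frames = config$phase_floor)
}

#' Feature vectors of one sequence
#'
#' With `"sequence"` granularity, one vector of the 13 descriptors per
#' channel over the span of the retained cycles (the whole sequence when
#' no cycle is found -- static techniques have none). With `"cycle"`
#' granularity, one vector per retained step segment.
#'
#' @param seq a [pose_sequence()].
#' @param config a [pipeline_config()].
#' @return matrix of feature rows with attribute `segments`.
#' @export
featurize_sequence <- function(seq, config = pipeline_config()) {
  filled <- fill_gaps(seq, window = config$gap_window)
  cs <- extract_channels(seq, config, .filled = filled)
  segres <- segment_sequence(seq, config, .filled = filled)
  kept <- segres$segments[segres$segments$kept, , drop = FALSE]
  spans <- if (config$granularity == "cycle" && nrow(kept) > 0) {
    lapply(seq_len(nrow(kept)),
           function(i) c(kept$start_frame[i], kept$end_frame[i]))
  } else if (nrow(kept) > 0) {
    list(c(min(kept$start_frame), max(kept$end_frame)))
  } else {
    list(c(0L, n_frames(seq) - 1L))
  }
  rows <- lapply(spans, function(sp) {
    idx <- (sp[1]:sp[2]) + 1L
    sub <- channel_set(lapply(cs$channels, function(x) x[idx]), cs$fs)
    build_feature_vector(sub)
  })
  out <- do.call(rbind, rows)
  attr(out, "segments") <- segres$segments
  attr(out, "spans") <- spans
  out
}

#' Raw resampled-series representation (no feature extraction)
#'
#' The ablation baseline: each base channel (no difference channels, no
#' descriptors) linearly resampled to `n_points` samples and
#' concatenated. This is what "feeding the joint motion data directly to
#' the classifier" means here.
#'
#' @param seq a [pose_sequence()].
#' @param config a [pipeline_config()].
#' @param n_points samples per channel after resampling.
#' @return one numeric row vector (matrix 1 x 8 * n_points).
#' @export
featurize_raw <- function(seq, config = pipeline_config(), n_points = 48) {
  cs <- extract_channels(seq, config, diff_channels = FALSE)
  v <- unlist(lapply(names(cs$channels), function(nm) {
    x <- cs$channels[[nm]]
    out <- stats::approx(seq_along(x), x, n = n_points)$y
    names(out) <- paste0(nm, "_t", seq_len(n_points))
    out
  }))
  matrix(v, nrow = 1, dimnames = list(NULL, names(v)))
}

#' Train the recognizer on a synthetic or loaded corpus
#'
#' Executes the full training pipeline -- smoothing, segmentation,
#' feature extraction, center standardization, SVM -- with stratified
#' k-fold cross-validation and a final holdout, as configured.
#'
#' @param corpus a `ski_corpus` from [generate_dataset()], or a list of
#'   entries each holding `sequence` (a [pose_sequence()]) and `label`.
#' @param config a [pipeline_config()].
#' @param seed seed for the fold assignment.
#' @param raw use the raw resampled-series baseline representation
#'   instead of descriptor features (for ablation).
#' @return list of class `ski_training`: `cv` (a `ski_cv`), `model`,
#'   `features`, `labels`, `config`.
#' @export
train_recognizer <- function(corpus, config = pipeline_config(), seed = 1,
                             raw = FALSE) {
  entries <- if (inherits(corpus, "ski_corpus")) corpus$sequences else corpus
  if (length(unique(vapply(entries, `[[`, character(1), "label"))) < 2) {
    stop("training error: corpus holds fewer than 2 classes")
  }
  feats <- list()
  labels <- character(0)
  for (e in entries) {
    m <- if (raw) featurize_raw(e$sequence, config)
         else featurize_sequence(e$sequence, config)
    feats[[length(feats) + 1L]] <- m
    labels <- c(labels, rep(e$label, nrow(m)))
  }
  x <- do.call(rbind, feats)
  cv <- cross_validate(x, labels, k = config$folds,
                       holdout = config$holdout, seed = seed,
                       fuse_knn = config$fuse_knn,
                       kernel = config$kernel, cost = config$cost)
  structure(list(cv = cv, model = cv$model, features = x, labels = labels,
                 config = config),
            class = "ski_training")
}

#' @export
print.ski_training <- function(x, ...) {
  cat("Ski recognition training run (", length(x$labels), " samples, ",
      ncol(x$features), " features, granularity '",
      x$config$granularity, "')\n", sep = "")
  print(x$cv)
  invisible(x)
}

#' Recognize sub-techniques in a pose sequence
#'
#' Runs the trained model over a sequence (or pose file): segmentation,
#' per-cycle (or whole-sequence) feature extraction, prediction. The
#' report lists every segment with its span, whether it was kept, and
#' the predicted label and score for analyzed spans. Deterministic for
#' identical inputs.
#'
#' @param x a [pose_sequence()] or a path to a pose file.
#' @param model a trained [ski_recognizer()] or `ski_training` result.
#' @param config a [pipeline_config()]; granularity controls whether
#'   labels are per cycle or per sequence.
#' @param ... passed to [read_pose_sequence()] when `x` is a path.
#' @return list of class `ski_recognition`: `labels`, `scores`, `spans`,
#'   `segments` (with drop reasons), `n_frames`.
#' @export
recognize <- function(x, model, config = pipeline_config(), ...) {
  seq <- if (inherits(x, "pose_sequence")) x else read_pose_sequence(x, ...)
  if (inherits(model, "ski_training")) model <- model$model
  stopifnot(inherits(model, "ski_recognizer"))
  if (n_frames(seq) == 0) {
    warning("empty pose sequence: nothing to recognize")
    return(structure(list(labels = factor(character(0),
                                          levels = model$levels),
                          scores = NULL, spans = list(),
                          segments = NULL, n_frames = 0L),
                     class = "ski_recognition"))
  }
  feats <- featurize_sequence(seq, config)
  pred <- predict(model, feats, fuse_knn = config$fuse_knn)
  segs <- attr(feats, "segments")
  if (!is.null(segs) && nrow(segs)) {
    segs$drop_reason <- ifelse(segs$kept, "",
                               "boundary or below median-step rule")
  }
  structure(list(labels = pred$labels, scores = pred$scores,
                 spans = attr(feats, "spans"), segments = segs,
                 n_frames = n_frames(seq)),
            class = "ski_recognition")
}

#' @export
print.ski_recognition <- function(x, ...) {
  if (x$n_frames == 0) {
    cat("Recognition report: empty sequence\n")
    return(invisible(x))
  }
  cat("Recognition report:", x$n_frames, "frames,",
      length(x$labels), "analyzed span(s)\n")
  for (i in seq_along(x$labels)) {
    sp <- x$spans[[i]]
    cat(sprintf("  frames %d-%d: %s (score %.3f)\n", sp[1], sp[2],
                as.character(x$labels[i]), max(x$scores[i, ])))
  }
  invisible(x)
}
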