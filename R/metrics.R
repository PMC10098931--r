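#' @name metrics
#' @title Pose-estimation evaluation metrics
#' @description
#' PCK (fraction of key points successfully detected), MPJPE (mean
#' per-joint position error) and MAEA (mean absolute error of a
#' joint-angle series, degrees). Each report can be serialized as JSON
#' via [metric_report_json()].
NULL

#' Percentage of correct key points
#'
#' The bare detection ratio `num_detected / num_truth`. A thresholded
#' variant -- count a detection as correct only when its position error is
#' within `threshold` -- is available by passing per-joint `errors`; it is
#' off by default because the plain ratio is the primary definition here.
#'
#' @param num_detected number of key points detected (ignored when
#'   `errors` is given).
#' @param num_truth number of ground-truth key points (> 0).
#' @param errors optional numeric vector of per-joint position errors for
#'   the thresholded variant.
#' @param threshold maximum error counted as correct (same units as
#'   `errors`), e.g. a fraction of a reference limb length.
#' @return list of class `metric_report` with `value` (ratio in \[0, 1\]),
#'   `percent`, and the counts used.
#' @export
pck <- function(num_detected = NULL, num_truth, errors = NULL,
                threshold = NULL) {
  if (num_truth <= 0) stop("metric error: num_truth must be positive")
  if (!is.null(errors)) {
    if (is.null(threshold)) stop("thresholded PCK needs a threshold")
    num_detected <- sum(errors <= threshold)
  }
  if (num_detected < 0 || num_detected > num_truth) {
    stop("metric error: num_detected must lie in [0, num_truth]")
  }
  ratio <- num_detected / num_truth
  structure(list(metric = "PCK", value = ratio, percent = 100 * ratio,
                 counts = list(num_detected = num_detected,
                               num_truth = num_truth)),
            class = "metric_report")
}

#' Mean per-joint position error
#'
#' Per frame, the mean Euclidean distance between predicted and
#' ground-truth positions over the joints observed in both sequences;
#' the sequence-level value is the mean over frames with at least one
#' common joint. Invariant to joint ordering.
#'
#' @param pred,truth aligned [pose_sequence()] objects with the same
#'   schema and frame count.
#' @return list of class `metric_report` with `value` (sequence mean),
#'   `per_frame`, and the joint counts used per frame.
#' @export
mpjpe <- function(pred, truth) {
  stopifnot(inherits(pred, "pose_sequence"), inherits(truth, "pose_sequence"))
  if (n_frames(pred) != n_frames(truth) ||
      !identical(pred$schema$keypoints, truth$schema$keypoints)) {
    stop("metric error: sequences must be aligned with the same schema")
  }
  nf <- n_frames(pred)
  per_frame <- rep(NA_real_, nf)
  counts <- integer(nf)
  d <- min(pred$dims, truth$dims)
  for (f in seq_len(nf)) {
    ok <- !apply(is.na(pred$coords[f, , seq_len(d), drop = FALSE]), 2, any) &
      !apply(is.na(truth$coords[f, , seq_len(d), drop = FALSE]), 2, any)
    counts[f] <- sum(ok)
    if (counts[f] == 0) next
    diff2 <- (pred$coords[f, ok, seq_len(d), drop = FALSE] -
                truth$coords[f, ok, seq_len(d), drop = FALSE])^2
    per_frame[f] <- mean(sqrt(apply(diff2, 2, sum)))
  }
  if (all(counts == 0)) stop("metric error: no jointly observed joints")
  structure(list(metric = "MPJPE", value = mean(per_frame, na.rm = TRUE),
                 per_frame = per_frame,
                 counts = list(joints_per_frame = counts)),
            class = "metric_report")
}

#' Mean absolute error of a joint-angle series
#'
#' `mean(|truth - pred|)` in degrees over aligned frames; symmetric in
#' its arguments. Frames where either series is missing are excluded
#' (their count is reported).
#'
#' @param pred_angles,truth_angles aligned numeric angle series (degrees).
#' @return list of class `metric_report`.
#' @export
maea <- function(pred_angles, truth_angles) {
  if (length(pred_angles) != length(truth_angles)) {
    stop("metric error: angle series lengths differ")
  }
  if (length(pred_angles) == 0) stop("metric error: empty series")
  ok <- !is.na(pred_angles) & !is.na(truth_angles)
  if (!any(ok)) stop("metric error: no jointly observed frames")
  structure(list(metric = "MAEA",
                 value = mean(abs(truth_angles[ok] - pred_angles[ok])),
                 counts = list(m = sum(ok), excluded = sum(!ok))),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(x$metric, ": ", format(x$value), "\n", sep = "")
  invisible(x)
}

#' Serialize a metric report as JSON
#' @param report a `metric_report`.
#' @return JSON string `{"metric": ..., "value": ..., "counts": {...}}`.
#' @export
metric_report_json <- function(report) {
  as.character(jsonlite::toJSON(
    list(metric = report$metric, value = report$value,
         counts = report$counts),
    auto_unbox = TRUE, digits = NA))
}
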