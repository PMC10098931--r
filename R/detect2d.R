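#' @name detect2d
#' @title Reference math for joint person/key-point detection
#'
#' @description
#' Pure-function implementations of the detection-side arithmetic used by
#' a YOLO-style joint detector of skier targets and key points: anchor-box
#' decoding, the three multi-task loss components and their weighted sum,
#' intersection-over-union, greedy non-maximum suppression, and the fusion
#' rule that assigns key-point detections to person candidate regions.
#' No network is involved; these functions exist as verifiable reference
#' math for testing and for post-processing stored detector output.
NULL

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Anchor prior
#'
#' @param w,h anchor width and height in pixels.
#' @param cell grid-cell coordinates `c(AKx, AKy)` of the anchor.
#' @param grid_scale output stride; one of 8, 16, 32, 64.
#' @return list of class `ski_anchor`.
#' @export
anchor <- function(w, h, cell = c(0, 0), grid_scale = 8) {
  if (!grid_scale %in% c(8, 16, 32, 64)) {
    stop("grid_scale must be one of 8, 16, 32, 64")
  }
  if (w <= 0 || h <= 0) stop("anchor dimensions must be positive")
  structure(list(w = w, h = h, cell = cell, grid_scale = grid_scale),
            class = "ski_anchor")
}

#' Default person anchors for the stride-8 grid
#'
#' Person targets are tall: anchors use a roughly 1:4 width-to-height
#' ratio -- (12, 20), (26, 46), (43, 102) at stride 8.
#' @return list of three [anchor()] objects.
#' @export
person_anchors_stride8 <- function() {
  list(anchor(12, 20), anchor(26, 46), anchor(43, 102))
}

#' Decode raw box regression against an anchor
#'
#' The center offsets use the bounded form `bx = (2*sigmoid(dx) - 0.5) + AKx`
#' (likewise in y), so the decoded center always lies within
#' (AKx - 0.5, AKx + 1.5); width and height scale the anchor by
#' `exp(dw)`, `exp(dh)`.
#'
#' @param raw list or numeric vector with elements `dx, dy, dw, dh`.
#' @param anc an [anchor()].
#' @return list of class `bbox` with center-format fields `bx, by, bw, bh`.
#' @export
decode_box <- function(raw, anc) {
  stopifnot(inherits(anc, "ski_anchor"))
  raw <- as.list(raw)
  v <- unlist(raw[c("dx", "dy", "dw", "dh")])
  if (length(v) != 4 || any(!is.finite(v))) {
    stop("raw prediction must have finite dx, dy, dw, dh")
  }
  bbox(bx = (2 * sigmoid(raw$dx) - 0.5) + anc$cell[1],
       by = (2 * sigmoid(raw$dy) - 0.5) + anc$cell[2],
       bw = anc$w * exp(raw$dw),
       bh = anc$h * exp(raw$dh))
}

#' Center-format bounding box
#' @param bx,by box center; @param bw,bh box width and height (positive).
#' @export
bbox <- function(bx, by, bw, bh) {
  if (bw <= 0 || bh <= 0) stop("box width and height must be positive")
  structure(list(bx = bx, by = by, bw = bw, bh = bh), class = "bbox")
}

#' Intersection over union of two center-format boxes
#'
#' @param b1,b2 [bbox()] objects.
#' @return overlap ratio in \[0, 1\].
#' @export
iou <- function(b1, b2) {
  corners <- function(b) c(b$bx - b$bw / 2, b$by - b$bh / 2,
                           b$bx + b$bw / 2, b$by + b$bh / 2)
  c1 <- corners(b1); c2 <- corners(b2)
  iw <- max(0, min(c1[3], c2[3]) - max(c1[1], c2[1]))
  ih <- max(0, min(c1[4], c2[4]) - max(c1[2], c2[2]))
  inter <- iw * ih
  union <- b1$bw * b1$bh + b2$bw * b2$bh - inter
  inter / union
}

#' Single detection
#' @param class_id class label (person or a key-point class).
#' @param score confidence in \[0, 1\].
#' @param box a [bbox()].
#' @export
detection <- function(class_id, score, box) {
  if (score < 0 || score > 1) stop("score must lie in [0, 1]")
  structure(list(class_id = class_id, score = score, box = box),
            class = "ski_detection")
}

#' Greedy non-maximum suppression
#'
#' Per class (by default): repeatedly keep the highest-scoring remaining
#' detection and delete every remaining detection of the same class whose
#' IoU with it exceeds `iou_threshold`. Output is sorted by score,
#' descending. Ties in score are broken by input order (first wins), so
#' the survivor set is independent of input order when scores are distinct.
#'
#' @param dets list of [detection()] objects.
#' @param iou_threshold overlap above which the lower-scoring box is removed.
#' @param class_agnostic suppress across classes instead of within each class.
#' @return list of surviving detections.
#' @export
nms <- function(dets, iou_threshold = 0.5, class_agnostic = FALSE) {
  if (length(dets) == 0) return(list())
  scores <- vapply(dets, function(d) d$score, numeric(1))
  ord <- order(-scores, seq_along(dets))
  alive <- rep(TRUE, length(dets))
  keep <- integer(0)
  for (i in ord) {
    if (!alive[i]) next
    keep <- c(keep, i)
    for (j in ord) {
      if (!alive[j] || j == i) next
      same <- class_agnostic || identical(dets[[j]]$class_id, dets[[i]]$class_id)
      if (same && iou(dets[[i]]$box, dets[[j]]$box) > iou_threshold) {
        alive[j] <- FALSE
      }
    }
    alive[i] <- FALSE
  }
  dets[keep]
}

loss_eps <- 1e-12

#' Class-score binary cross-entropy loss
#'
#' Summed elementwise BCE between predicted class probabilities and the
#' one-hot truth. Predictions exactly 0 or 1 are clamped by 1e-12 so the
#' logs stay finite.
#'
#' @param pred_probs predicted probabilities in (0, 1).
#' @param truth_onehot 0/1 vector of the same length.
#' @return non-negative scalar.
#' @export
class_loss_bce <- function(pred_probs, truth_onehot) {
  if (length(pred_probs) != length(truth_onehot)) {
    stop("prediction and truth lengths differ")
  }
  if (!all(truth_onehot %in% c(0, 1))) stop("truth must be 0/1")
  p <- pmin(pmax(pred_probs, loss_eps), 1 - loss_eps)
  -sum(truth_onehot * log(p) + (1 - truth_onehot) * log(1 - p))
}

#' Objectness (confidence) loss
#'
#' Treats the presence of a target in each (box, class) slot as a two-class
#' problem on the sigmoid of the raw logit, averaged over the number of
#' targets N:
#' `-(1/N) * sum_ij [ G_ij log sigma(C_ij) + (1 - G_ij) log(1 - sigma(C_ij)) ]`.
#'
#' @param logits numeric matrix of raw confidences `C_ij`.
#' @param truth 0/1 matrix `G_ij` of the same shape.
#' @param n_targets N; defaults to `sum(truth)`. When 0 the loss is defined
#'   as 0 with a warning.
#' @return non-negative scalar.
#' @export
confidence_loss <- function(logits, truth, n_targets = sum(truth)) {
  logits <- as.matrix(logits); truth <- as.matrix(truth)
  if (!all(dim(logits) == dim(truth))) stop("shape mismatch")
  if (!all(truth %in% c(0, 1))) stop("truth entries must be 0 or 1")
  if (n_targets == 0) {
    warning("no targets: confidence loss defined as 0")
    return(0)
  }
  p <- pmin(pmax(sigmoid(logits), loss_eps), 1 - loss_eps)
  -sum(truth * log(p) + (1 - truth) * log(1 - p)) / n_targets
}

#' Box-location squared-error loss
#'
#' Mean over boxes of
#' `(sigma(dx)-gx)^2 + (sigma(dy)-gy)^2 + (dw-gw)^2 + (dh-gh)^2`.
#' The sigmoid is applied to the raw center offsets only, exactly as the
#' loss is defined (this differs deliberately from the `2*sigma - 0.5`
#' decode used at inference; see the package vignette).
#'
#' @param preds list of raw predictions, each with `dx, dy, dw, dh`.
#' @param truths list of targets, each with `gx, gy, gw, gh`.
#' @return non-negative scalar.
#' @export
location_loss <- function(preds, truths) {
  if (length(preds) != length(truths)) stop("prediction/truth length mismatch")
  if (length(preds) == 0) stop("location loss needs at least one box")
  total <- 0
  for (i in seq_along(preds)) {
    p <- preds[[i]]; g <- truths[[i]]
    total <- total +
      (sigmoid(p$dx) - g$gx)^2 + (sigmoid(p$dy) - g$gy)^2 +
      (p$dw - g$gw)^2 + (p$dh - g$gh)^2
  }
  total / length(preds)
}

#' Weighted total 2D detection loss
#'
#' `a * L_class + b * L_box + c * L_obj` with default balancing
#' coefficients (0.6, 0.2, 0.3). The binding of weights to components is
#' explicit in the argument names so either reading of the loss naming can
#' be reproduced by reordering arguments.
#'
#' @param class_loss,box_loss,obj_loss non-negative component losses.
#' @param weights numeric length-3 vector `c(a, b, c)`, all non-negative.
#' @return scalar.
#' @export
total_2d_loss <- function(class_loss, box_loss, obj_loss,
                          weights = c(0.6, 0.2, 0.3)) {
  if (any(weights < 0)) stop("loss weights must be non-negative")
  if (any(c(class_loss, box_loss, obj_loss) < 0)) {
    stop("loss components must be non-negative")
  }
  weights[1] * class_loss + weights[2] * box_loss + weights[3] * obj_loss
}

#' Assign key-point detections to person candidate regions
#'
#' For each person box and each key-point class present among the
#' detections, the detection of that class whose box center is nearest
#' (Euclidean) to the person-box center is assigned. Exact distance ties
#' keep the earlier detection. Classes with no candidate are absent from
#' the result.
#'
#' @param keypoint_dets list of [detection()] objects (key-point classes).
#' @param person_boxes non-empty list of [bbox()] person candidate regions.
#' @return list (one element per person) of named lists mapping key-point
#'   class to the assigned detection.
#' @export
assign_keypoints_to_person <- function(keypoint_dets, person_boxes) {
  if (length(person_boxes) == 0) {
    stop("fusion error: no person candidate region")
  }
  lapply(person_boxes, function(pb) {
    out <- list()
    for (d in keypoint_dets) {
      dist <- sqrt((d$box$bx - pb$bx)^2 + (d$box$by - pb$by)^2)
      cls <- as.character(d$class_id)
      if (is.null(out[[cls]]) || dist < out[[cls]]$dist) {
        out[[cls]] <- list(det = d, dist = dist)
      }
    }
    lapply(out, function(e) e$det)
  })
}

#' Read/write detections as JSON lines
#'
#' One JSON object per line: `{"class": ..., "score": ..., "box": [bx,by,bw,bh]}`.
#' @param dets list of [detection()] objects.
#' @param path file path.
#' @return for reading, a list of detections; for writing, `path` invisibly.
#' @export
write_detections <- function(dets, path) {
  lines <- vapply(dets, function(d) {
    jsonlite::toJSON(list(class = d$class_id, score = d$score,
                          box = c(d$box$bx, d$box$by, d$box$bw, d$box$bh)),
                     auto_unbox = TRUE, digits = NA)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_detections
#' @export
read_detections <- function(path) {
  lines <- readLines(path)
  lapply(lines[nzchar(lines)], function(ln) {
    o <- jsonlite::fromJSON(ln)
    detection(o$class, o$score, bbox(o$box[1], o$box[2], o$box[3], o$box[4]))
  })
}
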