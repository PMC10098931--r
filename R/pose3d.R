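#' @name pose3d
#' @title 3D lifting losses, gap filling and joint angles
#'
#' @description
#' Reference math for the 3D side of the pipeline: the position and
#' rotation loss functions used when lifting 2D key points to 3D, filling
#' of unobserved key points from neighbouring frames (midpoint rule for
#' single-frame gaps, straight-line least squares for longer ones), and
#' joint-angle computation from three points.
NULL

#' Rotation matrix from per-axis angles
#'
#' Composes elemental rotations about the fixed x, y and z axes in that
#' written order: `R = Rx %*% Ry %*% Rz` (extrinsic convention). The
#' result is orthonormal with determinant +1.
#'
#' @param rx,ry,rz rotation angles in radians.
#' @return 3x3 rotation matrix.
#' @export
rotation_matrix <- function(rx, ry, rz) {
  if (any(!is.finite(c(rx, ry, rz)))) stop("angles must be finite")
  Rx <- matrix(c(1, 0, 0,
                 0, cos(rx), -sin(rx),
                 0, sin(rx), cos(rx)), 3, 3, byrow = TRUE)
  Ry <- matrix(c(cos(ry), 0, sin(ry),
                 0, 1, 0,
                 -sin(ry), 0, cos(ry)), 3, 3, byrow = TRUE)
  Rz <- matrix(c(cos(rz), -sin(rz), 0,
                 sin(rz), cos(rz), 0,
                 0, 0, 1), 3, 3, byrow = TRUE)
  Rx %*% Ry %*% Rz
}

#' Rotation compensation loss
#'
#' Mean over targets of the squared Frobenius distance between predicted
#' and ground-truth rotation matrices.
#'
#' @param preds,truths lists of 3x3 matrices, aligned.
#' @return non-negative scalar; 0 iff every pair matches exactly.
#' @export
rotation_loss <- function(preds, truths) {
  if (length(preds) != length(truths) || length(preds) == 0) {
    stop("prediction/truth lists must be aligned and non-empty")
  }
  s <- 0
  for (i in seq_along(preds)) {
    if (!all(dim(preds[[i]]) == c(3, 3)) || !all(dim(truths[[i]]) == c(3, 3))) {
      stop("rotation matrices must be 3x3")
    }
    s <- s + sum((preds[[i]] - truths[[i]])^2)
  }
  s / length(preds)
}

#' Position deviation loss
#'
#' Mean over joints of the squared Euclidean norm of the predicted-minus-
#' truth offset vectors.
#'
#' @param offsets list (or 3-column matrix) of per-joint offset vectors.
#' @return non-negative scalar; 0 iff all offsets are zero.
#' @export
location_loss_3d <- function(offsets) {
  if (is.matrix(offsets)) offsets <- asplit(offsets, 1)
  if (length(offsets) == 0) stop("location loss needs at least one joint")
  mean(vapply(offsets, function(o) sum(o^2), numeric(1)))
}

#' Total 3D lifting loss
#' @param loc,rot non-negative position and rotation losses.
#' @return their sum.
#' @export
total_3d_loss <- function(loc, rot) {
  if (loc < 0 || rot < 0) stop("loss components must be non-negative")
  loc + rot
}

#' Fill a single-frame gap by the neighbour midpoint
#'
#' For a key point unobserved in one frame but observed in the nearest
#' previous and next frames, returns the coordinate-wise midpoint
#' `(x0 + x1) / 2`. With `strict_halved_difference = TRUE` the halved
#' difference `(x1 - x0) / 2` is returned instead, for auditing against
#' formulations that print the rule that way; it is not a position and is
#' never used by the pipeline (see the vignette).
#'
#' @param seq a [pose_sequence()].
#' @param frame 0-based frame index of the missing observation.
#' @param keypoint key-point identifier.
#' @param strict_halved_difference reproduce the halved-difference form.
#' @return numeric coordinate vector of length `seq$dims`.
#' @export
fill_missing_midpoint <- function(seq, frame, keypoint,
                                  strict_halved_difference = FALSE) {
  stopifnot(inherits(seq, "pose_sequence"))
  ki <- match(keypoint, seq$schema$keypoints)
  if (is.na(ki)) stop("schema error: unknown key point '", keypoint, "'")
  fi <- frame + 1L
  obs <- which(!apply(is.na(seq$coords[, ki, , drop = FALSE]), 1, any))
  prev <- obs[obs < fi]
  nxt <- obs[obs > fi]
  if (length(prev) == 0 || length(nxt) == 0) {
    stop("gap-fill error: no observed neighbour on both sides")
  }
  x0 <- seq$coords[max(prev), ki, ]
  x1 <- seq$coords[min(nxt), ki, ]
  if (strict_halved_difference) (x1 - x0) / 2 else (x0 + x1) / 2
}

#' Fill a gap by straight-line least squares
#'
#' Fits an ordinary least-squares line per coordinate through the observed
#' frames within `window` frames on each side of the gap and evaluates it
#' at the gap frames. Motion between nearby frames at >= 50 Hz is close to
#' linear, which is what makes this reconstruction accurate.
#'
#' @param seq a [pose_sequence()].
#' @param gap integer vector of 0-based missing frame indices (contiguous).
#' @param keypoint key-point identifier.
#' @param window support half-width in frames on each side of the gap.
#' @return matrix `length(gap) x dims` of filled coordinates.
#' @export
fill_missing_least_squares <- function(seq, gap, keypoint, window = 5) {
  stopifnot(inherits(seq, "pose_sequence"))
  ki <- match(keypoint, seq$schema$keypoints)
  if (is.na(ki)) stop("schema error: unknown key point '", keypoint, "'")
  gap1 <- sort(gap) + 1L
  lo <- max(1L, min(gap1) - window)
  hi <- min(n_frames(seq), max(gap1) + window)
  support <- setdiff(lo:hi, gap1)
  support <- support[!apply(is.na(seq$coords[support, ki, , drop = FALSE]),
                            1, any)]
  if (sum(support < min(gap1)) < 2 || sum(support > max(gap1)) < 2) {
    stop("gap-fill error: need >= 2 observed frames on each side within the window")
  }
  out <- matrix(NA_real_, length(gap1), seq$dims)
  for (d in seq_len(seq$dims)) {
    y <- seq$coords[support, ki, d]
    fit <- stats::lm.fit(cbind(1, support), y)
    out[, d] <- cbind(1, gap1) %*% fit$coefficients
  }
  out
}

#' Fill all missing observations of a sequence
#'
#' Applies the gap-fill policy to every missing (frame, key point) entry:
#' single-frame gaps take the neighbour midpoint, longer gaps a
#' least-squares line over `window` frames each side; gaps touching the
#' sequence ends, or without enough support, are left missing. Observed
#' frames are never altered.
#'
#' @param seq a [pose_sequence()].
#' @param window least-squares support half-width in frames.
#' @return a [pose_sequence()] with fillable gaps filled.
#' @export
fill_gaps <- function(seq, window = 5) {
  stopifnot(inherits(seq, "pose_sequence"))
  mask <- missing_mask(seq)
  out <- seq
  for (ki in seq_along(seq$schema$keypoints)) {
    miss <- which(mask[, ki])
    if (length(miss) == 0) next
    runs <- split(miss, cumsum(c(1, diff(miss) != 1)))
    kp <- seq$schema$keypoints[ki]
    for (run in runs) {
      filled <- tryCatch({
        if (length(run) == 1L) {
          matrix(fill_missing_midpoint(seq, run - 1L, kp), 1)
        } else {
          fill_missing_least_squares(seq, run - 1L, kp, window = window)
        }
      }, error = function(e) NULL)
      if (!is.null(filled)) {
        for (d in seq_len(seq$dims)) out$coords[run, ki, d] <- filled[, d]
      }
    }
  }
  out
}

#' Joint angle at a vertex
#'
#' The included angle at `a2` between the limb vectors `a2 -> a1` and
#' `a2 -> a3`: `acos` of their normalized inner product, with the argument
#' clamped to \[-1, 1\]. Reported in degrees in \[0, 180\]. Invariant to any
#' rigid motion or uniform scaling applied to all three points.
#'
#' @param a1,a2,a3 coordinate vectors (2D or 3D): proximal point, vertex,
#'   distal point.
#' @return angle in degrees.
#' @export
joint_angle <- function(a1, a2, a3) {
  u <- a1 - a2
  v <- a3 - a2
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("angle error: degenerate triplet (zero-length limb)")
  ct <- sum(u * v) / (nu * nv)
  acos(pmin(pmax(ct, -1), 1)) * 180 / pi
}

#' Per-frame joint-angle series for every configured triplet
#'
#' Frames in which any member of a triplet is missing yield a missing
#' angle; nothing is interpolated here (use [fill_gaps()] first if
#' desired).
#'
#' @param seq a [pose_sequence()].
#' @param schema schema whose `angle_triplets` to evaluate; defaults to the
#'   sequence's own.
#' @return data frame with columns `frame`, one column per triplet name
#'   (degrees), suitable for export as CSV.
#' @export
angle_series <- function(seq, schema = seq$schema) {
  stopifnot(inherits(seq, "pose_sequence"))
  nf <- n_frames(seq)
  out <- data.frame(frame = seq_len(nf) - 1L)
  for (nm in names(schema$angle_triplets)) {
    trip <- schema$angle_triplets[[nm]]
    ki <- match(trip, seq$schema$keypoints)
    u <- seq$coords[, ki[1], , drop = FALSE] - seq$coords[, ki[2], , drop = FALSE]
    v <- seq$coords[, ki[3], , drop = FALSE] - seq$coords[, ki[2], , drop = FALSE]
    dim(u) <- dim(v) <- c(nf, seq$dims)
    nu <- sqrt(rowSums(u^2)); nv <- sqrt(rowSums(v^2))
    ct <- rowSums(u * v) / (nu * nv)
    vals <- acos(pmin(pmax(ct, -1), 1)) * 180 / pi
    vals[!is.finite(ct)] <- NA_real_   # missing member or zero-length limb
    out[[nm]] <- vals
  }
  out
}
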