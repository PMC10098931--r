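#' @name segmentation
#' @title Motion-cycle segmentation from smoothed trajectories
#'
#' @description
#' A skiing stride or poling cycle shows up as a valley in the right
#' trajectory channel: the landing of a foot in the (detrended) ankle
#' forward coordinate, a pole plant in the pole-tip vertical coordinate.
#' The segmentation machinery finds prominent valleys, merges valleys
#' closer than a minimum frame gap (jitter produces redundant poles),
#' cuts the track into one step segment per consecutive valley pair, and
#' removes implausible segments: the incomplete first and last ones, and
#' any abnormally short ones relative to the per-sequence median step
#' length.
NULL

#' Backward finite difference
#'
#' `out[t] = x[t] - x[t-1]` for t >= 2; the first element is defined as 0
#' so the output has the input's length and the cumulative sum of the
#' output plus `x[1]` reconstructs the input.
#'
#' @param track numeric vector, length >= 2.
#' @return numeric vector of per-frame increments.
#' @export
backward_diff <- function(track) {
  if (length(track) < 2) stop("backward_diff needs at least 2 samples")
  c(0, diff(track))
}

#' Detect prominent valleys
#'
#' Local minima of the track, restricted to strictly interior frames,
#' with topographic prominence of at least `prominence` (for a valley:
#' the smaller of the two climbs needed to escape it to either side
#' before reaching a deeper point). Plateau minima report their central
#' frame. The default prominence is 10% of the track's peak-to-peak
#' range; smoothed input is recommended.
#'
#' @param track numeric vector.
#' @param prominence minimum prominence in track units, or `NULL` for the
#'   10% peak-to-peak default.
#' @return integer vector of 0-based valley frame indices.
#' @export
detect_valleys <- function(track, prominence = NULL) {
  x <- as.numeric(track)
  n <- length(x)
  if (n < 3) return(integer(0))
  if (is.null(prominence)) prominence <- 0.1 * diff(range(x))
  y <- -x  # work on peaks of the negated track
  # candidate peaks incl. plateau centers
  cand <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (y[i] > y[i - 1L]) {
      j <- i
      while (j < n && y[j + 1L] == y[i]) j <- j + 1L
      if (j < n && y[j + 1L] < y[i]) {
        cand <- c(cand, as.integer(floor((i + j) / 2)))
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (length(cand) == 0) return(integer(0))
  keep <- vapply(cand, function(p) {
    # climb down from peak p on each side until a higher point appears
    left_min <- if (p > 1) min(y[1:(p - 1)]) else y[p]
    right_min <- if (p < n) min(y[(p + 1):n]) else y[p]
    higher_l <- which(y[seq_len(p - 1)] > y[p])
    base_l <- if (length(higher_l)) min(y[(max(higher_l) + 1):(p - 1)]) else left_min
    higher_r <- which(y[(p + 1):n] > y[p]) + p
    base_r <- if (length(higher_r)) min(y[(p + 1):(min(higher_r) - 1)]) else right_min
    prom <- y[p] - max(base_l, base_r)
    prom >= prominence
  }, logical(1))
  cand[keep] - 1L
}

#' Merge valleys closer than a minimum frame gap
#'
#' Any two adjacent valleys fewer than `min_gap` frames apart are
#' combined into the one at which the track is deeper (ties keep the
#' earlier valley). The operation is idempotent and its output has all
#' pairwise gaps >= `min_gap`.
#'
#' @param frames sorted integer vector of 0-based valley frames.
#' @param track the track the valleys were detected on (for depths).
#' @param min_gap minimum allowed frame separation (default 60).
#' @return merged 0-based valley frames.
#' @export
merge_valleys <- function(frames, track, min_gap = 60) {
  if (is.unsorted(frames)) stop("valley frames must be sorted")
  out <- integer(0)
  for (f in frames) {
    if (length(out) == 0 || f - out[length(out)] >= min_gap) {
      out <- c(out, f)
    } else {
      prev <- out[length(out)]
      # keep the deeper valley; tie -> earlier
      if (track[f + 1L] < track[prev + 1L]) out[length(out)] <- f
    }
  }
  out
}

#' Cut a track into step segments between consecutive valleys
#'
#' One segment per consecutive valley pair. Two length variants are
#' reported: the absolute difference of the track value at the two
#' valleys (the forward step size in pixels when the track is the ankle
#' x coordinate) and the Euclidean distance in the (frame-scaled time,
#' track) plane; the duration is the frame gap divided by the frame rate.
#'
#' @param valleys 0-based valley frames (>= 2 of them, else empty result).
#' @param track the segmented track.
#' @param fs frame rate in Hz.
#' @return data frame with columns `start_frame`, `end_frame`,
#'   `length_px`, `length_euclid`, `duration_s`, `kept`, `flagged_short`.
#' @export
segment_steps <- function(valleys, track, fs) {
  if (length(valleys) < 2) {
    return(data.frame(start_frame = integer(0), end_frame = integer(0),
                      length_px = numeric(0), length_euclid = numeric(0),
                      duration_s = numeric(0), kept = logical(0),
                      flagged_short = logical(0)))
  }
  s <- valleys[-length(valleys)]
  e <- valleys[-1]
  dx <- abs(track[e + 1L] - track[s + 1L])
  data.frame(start_frame = s, end_frame = e,
             length_px = dx,
             length_euclid = sqrt(dx^2 + ((e - s))^2),
             duration_s = (e - s) / fs,
             kept = TRUE,
             flagged_short = FALSE)
}

#' Filter out implausible step segments
#'
#' Drops the first and last segments of a sequence (incomplete by
#' construction) and any interior segment whose pixel length falls more
#' than `median_margin` below the median pixel length of the sequence.
#' Segments spanning fewer than `min_phase_frames` frames (a complete
#' motion phase is generally longer) are flagged, not dropped.
#'
#' @param segments data frame from [segment_steps()].
#' @param median_margin pixels below the median at which a step is
#'   considered spurious (default 50).
#' @param min_phase_frames flagging floor on segment span (default 150).
#' @param drop_boundary drop the first and last segments (default TRUE).
#' @return the segments data frame with `kept` and `flagged_short` updated;
#'   rows are retained so the removal reasons stay auditable.
#' @export
filter_steps <- function(segments, median_margin = 50,
                         min_phase_frames = 150, drop_boundary = TRUE) {
  seg <- segments
  n <- nrow(seg)
  if (n == 0) return(seg)
  kept <- rep(TRUE, n)
  if (drop_boundary) {
    kept[1] <- FALSE
    kept[n] <- FALSE
  }
  if (any(kept)) {
    med <- stats::median(seg$length_px[kept])
    kept <- kept & !(seg$length_px < med - median_margin)
  }
  seg$kept <- kept
  seg$flagged_short <- (seg$end_frame - seg$start_frame) < min_phase_frames
  seg
}

#' Valley-based segmentation of one trajectory channel
#'
#' Convenience wrapper: smooth (optional), optionally remove the linear
#' trend (needed for monotonically advancing coordinates such as ankle x),
#' detect and merge valleys, and cut into filtered step segments.
#'
#' @param track numeric trajectory channel.
#' @param fs frame rate in Hz.
#' @param spec optional [filter_spec()]; default third-order 14 Hz
#'   zero-phase design at `fs`.
#' @param detrend remove the least-squares linear trend before valley
#'   detection.
#' @param prominence passed to [detect_valleys()].
#' @param min_gap passed to [merge_valleys()].
#' @param ... passed to [filter_steps()].
#' @return list with `valleys` (0-based frames) and `segments` (data frame).
#' @export
segment_cycles <- function(track, fs, spec = NULL, detrend = FALSE,
                           prominence = NULL, min_gap = 60, ...) {
  x <- as.numeric(track)
  if (is.null(spec)) spec <- filter_spec(fs = fs)
  xs <- butterworth_filter(x, spec)
  sig <- xs
  if (detrend) {
    t0 <- seq_along(sig)
    sig <- sig - stats::lm.fit(cbind(1, t0), sig)$fitted.values
  }
  v <- detect_valleys(sig, prominence = prominence)
  v <- merge_valleys(v, sig, min_gap = min_gap)
  seg <- segment_steps(v, xs, fs)
  seg <- filter_steps(seg, ...)
  list(valleys = v, segments = seg, smoothed = xs, detection_signal = sig)
}
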