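# Shared fixtures and light oracles for the test suite. The corpus used
# by the end-to-end tests is expensive to build, so it is computed once
# per test run and memoized here.

.fixture_env <- new.env(parent = emptyenv())

# The study corpus: 79 DP + 66 DS + 75 DT sequences, seed 42, default
# simulator parameters, plus the descriptor features and the raw
# resampled-series representation of every sequence.
study_corpus <- function() {
  if (is.null(.fixture_env$corpus)) {
    .fixture_env$corpus <- generate_dataset(c(DP = 79, DS = 66, DT = 75),
                                            seed = 42)
  }
  .fixture_env$corpus
}

study_features <- function() {
  if (is.null(.fixture_env$features)) {
    corpus <- study_corpus()
    cfg <- pipeline_config()
    rows <- lapply(corpus$sequences,
                   function(e) featurize_sequence(e$sequence, cfg))
    .fixture_env$features <- do.call(rbind, rows)
    .fixture_env$labels <- vapply(corpus$sequences, `[[`, character(1),
                                  "label")
  }
  list(x = .fixture_env$features, y = .fixture_env$labels)
}

study_raw_features <- function() {
  if (is.null(.fixture_env$raw_features)) {
    corpus <- study_corpus()
    cfg <- pipeline_config()
    rows <- lapply(corpus$sequences,
                   function(e) featurize_raw(e$sequence, cfg))
    .fixture_env$raw_features <- do.call(rbind, rows)
  }
  .fixture_env$raw_features
}

# A tiny 2-keypoint schema for I/O tests.
toy_schema <- function() {
  ski_schema(keypoints = c("left_ankle", "right_ankle"),
             bilateral_pairs = list(c("left_ankle", "right_ankle")),
             angle_triplets = list(),
             pole_tips = character(0))
}

toy_sequence <- function(n = 3, dims = 2, fs = 60, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  coords <- array(stats::rnorm(n * 2 * dims), c(n, 2, dims))
  pose_sequence(coords, fs, toy_schema())
}

expect_sequences_equal <- function(a, b, tol = 1e-12) {
  expect_equal(n_frames(a), n_frames(b))
  expect_equal(a$dims, b$dims)
  expect_equal(a$frame_rate, b$frame_rate)
  expect_equal(a$coords, b$coords, tolerance = tol)
}

# Independent brute-force NMS used as the oracle: per class, repeatedly
# take the best remaining score and drop overlapping same-class boxes.
nms_oracle <- function(dets, thr) {
  survivors <- list()
  classes <- unique(vapply(dets, function(d) as.character(d$class_id),
                           character(1)))
  for (cl in classes) {
    idx <- which(vapply(dets, function(d) identical(as.character(d$class_id),
                                                    cl), logical(1)))
    while (length(idx)) {
      sc <- vapply(dets[idx], function(d) d$score, numeric(1))
      best <- idx[which.max(sc)]
      survivors[[length(survivors) + 1L]] <- best
      idx <- idx[idx != best]
      ok <- vapply(idx, function(j) {
        iou_oracle_boxes(dets[[best]]$box, dets[[j]]$box) <= thr
      }, logical(1))
      idx <- idx[ok]
    }
  }
  sort(unlist(survivors))
}

# corner-form IoU used by the NMS oracle (independent of iou())
iou_oracle_boxes <- function(b1, b2) {
  x1 <- max(b1$bx - b1$bw / 2, b2$bx - b2$bw / 2)
  x2 <- min(b1$bx + b1$bw / 2, b2$bx + b2$bw / 2)
  y1 <- max(b1$by - b1$bh / 2, b2$by - b2$bh / 2)
  y2 <- min(b1$by + b1$bh / 2, b2$by + b2$bh / 2)
  inter <- max(0, x2 - x1) * max(0, y2 - y1)
  inter / (b1$bw * b1$bh + b2$bw * b2$bh - inter)
}

random_detections <- function(n, n_classes = 3) {
  lapply(seq_len(n), function(i) {
    detection(class_id = sample(letters[seq_len(n_classes)], 1),
              score = round(stats::runif(1), 6),
              box = bbox(stats::runif(1, 0, 20), stats::runif(1, 0, 20),
                         stats::runif(1, 1, 10), stats::runif(1, 1, 10)))
  })
}

# Table-style descriptor oracle written as explicit loops, kept deliberately
# separate from time_features().
time_features_oracle <- function(x) {
  n <- length(x)
  mu <- sum(x) / n
  st <- sqrt(sum((x - mu)^2) / n)
  rm_ <- sqrt(sum(abs(x)^2) / n)
  c(Max = max(x), Min = min(x), mean = mu, pk = max(x) - min(x), st = st,
    ku = if (st > 0) sum((x - mu)^4) / ((n - 1) * st^4) else 0,
    sk = if (st > 0) sum((x - mu)^3) / (n * st^3) else 0,
    rm = rm_,
    S = if (rm_ > 0) rm_ / (sum(abs(x)) / n) else 0,
    C = if (rm_ > 0) (max(x) - min(x)) / rm_ else 0)
}
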