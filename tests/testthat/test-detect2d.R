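test_that("decode_box reproduces the bounded-offset anchor decode", {
  # sigmoid(dx) = 0.25 makes the offset term vanish
  raw <- list(dx = log(0.25 / 0.75), dy = 0, dw = 0, dh = 0)
  b <- decode_box(raw, anchor(26, 46, cell = c(10, 4)))
  expect_equal(b$bx, 10)
  expect_equal(b$bw, 26)
  expect_equal(b$bh, 46)
  set.seed(1)
  for (i in 1:100) {
    raw <- list(dx = rnorm(1), dy = rnorm(1), dw = rnorm(1), dh = rnorm(1))
    anc <- anchor(runif(1, 5, 50), runif(1, 5, 120),
                  cell = c(sample(0:40, 1), sample(0:40, 1)))
    b <- decode_box(raw, anc)
    sig <- function(v) 1 / (1 + exp(-v))
    expect_equal(b$bx, 2 * sig(raw$dx) - 0.5 + anc$cell[1])
    expect_equal(b$by, 2 * sig(raw$dy) - 0.5 + anc$cell[2])
    expect_equal(b$bw, anc$w * exp(raw$dw))
    expect_equal(b$bh, anc$h * exp(raw$dh))
    # decoded center stays within the 2-sigmoid offset range of the cell
    expect_gt(b$bx, anc$cell[1] - 0.5); expect_lt(b$bx, anc$cell[1] + 1.5)
    expect_gt(b$by, anc$cell[2] - 0.5); expect_lt(b$by, anc$cell[2] + 1.5)
  }
  expect_error(decode_box(list(dx = NaN, dy = 0, dw = 0, dh = 0),
                          anchor(10, 40)), "finite")
})

test_that("iou matches a pixel-rasterization oracle on integer boxes", {
  b <- bbox(5, 5, 4, 4)
  expect_equal(iou(b, b), 1.0)
  expect_equal(iou(bbox(0, 0, 2, 2), bbox(10, 10, 2, 2)), 0.0)
  set.seed(2)
  rasterize <- function(b, grid) {
    (grid$x >= b$bx - b$bw / 2) & (grid$x < b$bx + b$bw / 2) &
      (grid$y >= b$by - b$bh / 2) & (grid$y < b$by + b$bh / 2)
  }
  grid <- expand.grid(x = seq(-8, 30, by = 0.5) + 0.25,
                      y = seq(-8, 30, by = 0.5) + 0.25)
  for (i in 1:25) {
    b1 <- bbox(sample(2:20, 1), sample(2:20, 1), sample(1:8, 1) * 2,
               sample(1:8, 1) * 2)
    b2 <- bbox(sample(2:20, 1), sample(2:20, 1), sample(1:8, 1) * 2,
               sample(1:8, 1) * 2)
    m1 <- rasterize(b1, grid); m2 <- rasterize(b2, grid)
    expect_equal(iou(b1, b2), sum(m1 & m2) / sum(m1 | m2), tolerance = 1e-12)
  }
})

test_that("nms keeps the right survivors", {
  d1 <- detection("person", 0.9, bbox(5, 5, 4, 4))
  expect_equal(nms(list(d1), 0.5), list(d1))
  d2 <- detection("person", 0.8, bbox(5, 5, 4, 4))
  out <- nms(list(d2, d1), 0.5)
  expect_length(out, 1)
  expect_equal(out[[1]]$score, 0.9)
})

test_that("nms equals the brute-force oracle and is order-independent", {
  set.seed(3)
  for (trial in 1:60) {
    dets <- random_detections(sample(2:50, 1))
    thr <- runif(1, 0.2, 0.7)
    got <- nms(dets, thr)
    keys <- function(ds) sort(vapply(ds, function(d)
      paste(d$class_id, d$score, d$box$bx, d$box$by), character(1)))
    expect_identical(keys(got), keys(dets[nms_oracle(dets, thr)]))
    # order independence for distinct scores
    perm <- sample(seq_along(dets))
    expect_identical(keys(nms(dets[perm], thr)), keys(got))
    # survivors pairwise below threshold within class
    for (i in seq_along(got)) for (j in seq_len(i - 1L)) {
      if (identical(got[[i]]$class_id, got[[j]]$class_id)) {
        expect_lte(iou(got[[i]]$box, got[[j]]$box), thr)
      }
    }
  }
})

test_that("class BCE loss matches its closed forms and the loop oracle", {
  onehot <- c(1, 0, 0)
  near <- pmin(pmax(onehot, 1e-12), 1 - 1e-12)
  expect_lt(class_loss_bce(near, onehot), 1e-9)
  expect_equal(class_loss_bce(c(0.5, 0.5), c(1, 0)), 2 * log(2))
  set.seed(4)
  for (i in 1:30) {
    p <- runif(5, 0.01, 0.99)
    g <- rbinom(5, 1, 0.5)
    expect_equal(class_loss_bce(p, g),
                 -sum(g * log(p) + (1 - g) * log(1 - p)), tolerance = 1e-12)
  }
  expect_error(class_loss_bce(c(0.5), c(0.2)), "0/1")
})

test_that("confidence loss averages BCE of sigmoided logits over targets", {
  expect_equal(confidence_loss(matrix(0), matrix(1)), log(2))
  big <- matrix(c(40, -40), 1); g <- matrix(c(1, 0), 1)
  expect_lt(confidence_loss(big, g, n_targets = 1), 1e-9)
  expect_warning(v <- confidence_loss(matrix(-3), matrix(0)), "no targets")
  expect_equal(v, 0)
  set.seed(5)
  for (i in 1:20) {
    L <- matrix(rnorm(12), 3)
    G <- matrix(rbinom(12, 1, 0.4), 3)
    N <- max(1, sum(G))
    acc <- 0
    for (r in 1:3) for (cc in 1:4) {
      p <- 1 / (1 + exp(-L[r, cc]))
      acc <- acc - (G[r, cc] * log(p) + (1 - G[r, cc]) * log(1 - p))
    }
    expect_equal(confidence_loss(L, G, n_targets = N), acc / N,
                 tolerance = 1e-10)
  }
})

test_that("location loss is the mean of the four squared terms", {
  sig <- function(v) 1 / (1 + exp(-v))
  p <- list(dx = 0.3, dy = -1, dw = 0.5, dh = 2)
  g <- list(gx = sig(0.3), gy = sig(-1), gw = 0.5, gh = 2)
  expect_equal(location_loss(list(p), list(g)), 0)
  p1 <- list(dx = 1e9, dy = 1e9, dw = 1, dh = 1)   # sigmoids saturate at 1
  g1 <- list(gx = 0, gy = 0, gw = 0, gh = 0)
  expect_equal(location_loss(list(p1), list(g1)), 4.0)
  set.seed(6)
  preds <- lapply(1:7, function(i) list(dx = rnorm(1), dy = rnorm(1),
                                        dw = rnorm(1), dh = rnorm(1)))
  truths <- lapply(1:7, function(i) list(gx = runif(1), gy = runif(1),
                                         gw = rnorm(1), gh = rnorm(1)))
  acc <- 0
  for (i in 1:7) {
    acc <- acc + (sig(preds[[i]]$dx) - truths[[i]]$gx)^2 +
      (sig(preds[[i]]$dy) - truths[[i]]$gy)^2 +
      (preds[[i]]$dw - truths[[i]]$gw)^2 +
      (preds[[i]]$dh - truths[[i]]$gh)^2
  }
  expect_equal(location_loss(preds, truths), acc / 7, tolerance = 1e-12)
  expect_error(location_loss(preds, truths[1:3]), "mismatch")
})

test_that("total 2D loss is the weighted sum with default (0.6, 0.2, 0.3)", {
  expect_equal(total_2d_loss(1, 1, 1), 1.1)
  expect_equal(total_2d_loss(0, 0, 0), 0)
  set.seed(7)
  for (i in 1:20) {
    comps <- runif(3, 0, 5); w <- runif(3, 0, 2)
    expect_equal(total_2d_loss(comps[1], comps[2], comps[3], w),
                 sum(w * comps))
  }
  expect_error(total_2d_loss(1, 1, 1, weights = c(-1, 0, 0)), "non-negative")
})

test_that("keypoint-to-person fusion picks the nearest candidate per class", {
  pb <- bbox(50, 50, 40, 160)
  near <- detection("left_ankle", 0.8, bbox(53, 54, 4, 4))   # 5 px away
  far <- detection("left_ankle", 0.9, bbox(80, 90, 4, 4))    # 50 px away
  out <- assign_keypoints_to_person(list(far, near), list(pb))
  expect_equal(out[[1]]$left_ankle$box$bx, 53)
  expect_error(assign_keypoints_to_person(list(near), list()),
               "fusion error")
  set.seed(8)
  classes <- paste0("kp", 1:19)
  for (trial in 1:20) {
    persons <- lapply(seq_len(sample(1:3, 1)), function(i)
      bbox(runif(1, 0, 100), runif(1, 0, 100), 40, 160))
    dets <- lapply(seq_len(sample(5:40, 1)), function(i)
      detection(sample(classes, 1), runif(1),
                bbox(runif(1, 0, 100), runif(1, 0, 100), 4, 4)))
    got <- assign_keypoints_to_person(dets, persons)
    for (pi in seq_along(persons)) {
      # each class at most once, and each assignment is the true argmin
      expect_false(anyDuplicated(names(got[[pi]])) > 0)
      for (cls in names(got[[pi]])) {
        cand <- Filter(function(d) identical(as.character(d$class_id), cls),
                       dets)
        dists <- vapply(cand, function(d)
          sqrt((d$box$bx - persons[[pi]]$bx)^2 +
                 (d$box$by - persons[[pi]]$by)^2), numeric(1))
        expect_equal(got[[pi]][[cls]]$box$bx,
                     cand[[which.min(dists)]]$box$bx)
      }
    }
  }
})

test_that("detections round trip through JSON lines", {
  dets <- list(detection("person", 0.9, bbox(5, 6, 7, 8)),
               detection("left_ankle", 0.25, bbox(1.5, 2.5, 3, 3)))
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_detections(dets, path)
  r <- read_detections(path)
  expect_equal(r[[2]]$class_id, "left_ankle")
  expect_equal(r[[1]]$box$bh, 8)
  expect_equal(r[[2]]$score, 0.25)
})
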