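test_that("backward difference telescopes back to the input", {
  expect_equal(backward_diff(rep(4, 10)), rep(0, 10))
  expect_equal(backward_diff(seq(0, 18, by = 2)), c(0, rep(2, 9)))
  set.seed(1)
  x <- rnorm(50)
  expect_equal(cumsum(backward_diff(x)) + x[1], x, tolerance = 1e-12)
  expect_error(backward_diff(1), "at least 2")
})

test_that("valley detection finds analytic minima", {
  x <- (seq(-10, 10))^2
  expect_equal(detect_valleys(x, prominence = 1), 10)   # vertex, 0-based
  fs <- 60
  t <- 0:(fs * 4 - 1)
  sine <- sin(2 * pi * 1 * t / fs)    # minima at t = 45, 105, 165, 225
  v <- detect_valleys(sine)
  expect_length(v, 4)
  expect_true(all(abs(v - c(45, 105, 165, 225)) <= 1))
  expect_length(detect_valleys(seq_len(100)), 0)   # monotone ramp
})

test_that("valleys on plateaus report the central frame", {
  x <- c(5, 4, 3, 1, 1, 1, 3, 4, 5)
  expect_equal(detect_valleys(x, prominence = 1), 4)
})

test_that("valley merging keeps the deeper valley and is idempotent", {
  track <- rep(1, 400)
  track[c(101, 141, 301)] <- 0    # equal depths at frames 100, 140, 300
  expect_equal(merge_valleys(c(100, 140, 300), track), c(100, 300))
  expect_equal(merge_valleys(c(100, 180, 300), track), c(100, 180, 300))
  track2 <- rep(1, 400); track2[141] <- -1; track2[101] <- 0
  expect_equal(merge_valleys(c(100, 140, 300), track2), c(140, 300))
  set.seed(2)
  for (i in 1:20) {
    v <- sort(sample(0:999, 25))
    tr <- rnorm(1000)
    m <- merge_valleys(v, tr, min_gap = 60)
    expect_true(all(diff(m) >= 60))
    expect_equal(merge_valleys(m, tr, min_gap = 60), m)
  }
})

test_that("step segments carry both length variants and exact durations", {
  fs <- 60
  track <- seq(0, 399)    # ramp, 1 px/frame
  seg <- segment_steps(c(0, 120, 240), track, fs)
  expect_equal(nrow(seg), 2)
  expect_equal(seg$length_px[1], 120)
  expect_equal(seg$duration_s[1], 2.0)
  expect_equal(seg$length_euclid[1], sqrt(120^2 + 120^2))
  expect_equal(nrow(segment_steps(c(5), track, fs)), 0)
  for (k in 2:5) {
    expect_equal(nrow(segment_steps(seq(0, by = 100, length.out = k + 1),
                                    track, fs)), k)
  }
})

test_that("step filtering drops boundaries and abnormally short steps", {
  seg5 <- data.frame(start_frame = seq(0, 800, by = 200),
                     end_frame = seq(200, 1000, by = 200),
                     length_px = rep(200, 5), length_euclid = rep(283, 5),
                     duration_s = rep(200 / 60, 5), kept = TRUE,
                     flagged_short = FALSE)
  out5 <- filter_steps(seg5)
  expect_equal(which(out5$kept), 2:4)

  lengths <- c(150, 200, 200, 90, 200, 150)
  seg6 <- data.frame(start_frame = seq(0, by = 200, length.out = 6),
                     end_frame = seq(200, by = 200, length.out = 6),
                     length_px = lengths, length_euclid = lengths,
                     duration_s = rep(3, 6), kept = TRUE,
                     flagged_short = FALSE)
  out6 <- filter_steps(seg6)
  # boundaries gone; interior median is 200, so the 90 px step is removed
  expect_equal(which(out6$kept), c(2, 3, 5))

  set.seed(3)
  for (i in 1:20) {
    n <- sample(4:12, 1)
    lp <- runif(n, 50, 400)
    seg <- data.frame(start_frame = seq(0, by = 200, length.out = n),
                      end_frame = seq(200, by = 200, length.out = n),
                      length_px = lp, length_euclid = lp,
                      duration_s = rep(3, n), kept = TRUE,
                      flagged_short = FALSE)
    out <- filter_steps(seg)
    med <- median(lp[2:(n - 1)])
    expect_true(all(out$length_px[out$kept] >= med - 50))
  }
})

test_that("segments shorter than the phase floor are flagged, not dropped", {
  seg <- data.frame(start_frame = c(0, 100, 300, 600),
                    end_frame = c(100, 300, 600, 700),
                    length_px = rep(200, 4), length_euclid = rep(200, 4),
                    duration_s = c(100, 200, 300, 100) / 60, kept = TRUE,
                    flagged_short = FALSE)
  out <- filter_steps(seg)
  expect_equal(out$flagged_short, c(TRUE, FALSE, FALSE, TRUE))
  expect_true(out$kept[2])
})

test_that("segmentation recovers the simulator cycle count on clean data", {
  for (act in c("DP", "DS")) {
    for (ph in c(0, 1.1, 2.7, 4.4)) {
      g <- generate_sequence(sim_config(act, phase = ph))
      sr <- segment_sequence(g$sequence)
      expect_length(sr$valleys, length(g$truth$cycle_boundaries))
    }
  }
})

test_that("segmentation stays within one cycle at the default noise level", {
  for (s in 1:4) {
    cfg <- sim_config("DS", phase = s, seed = s)
    g <- generate_sequence(cfg)
    cor <- corrupt(g$sequence, cfg)
    sr <- segment_sequence(cor$sequence)
    expect_lte(abs(length(sr$valleys) - length(g$truth$cycle_boundaries)), 1)
  }
})
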