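test_that("technique templates realize the phase taxonomy", {
  dp <- generate_sequence(sim_config("DP"))
  a <- dp$truth$angles
  expect_equal(a$left_elbow, a$right_elbow)       # bilateral: identical
  expect_equal(a$left_knee, a$right_knee)

  ds <- generate_sequence(sim_config("DS"))
  le <- ds$truth$angles$left_elbow
  re <- ds$truth$angles$right_elbow
  half <- round(60 / (2 * 0.9))
  n <- length(le)
  # anti-phase: maximal correlation at a half-period shift
  expect_gt(cor(le[(half + 1):n], re[1:(n - half)]), 0.99)
  expect_lt(cor(le - mean(le), re - mean(re)), -0.99)

  dt <- generate_sequence(sim_config("DT"))
  expect_lt(sd(dt$truth$angles$left_elbow), 5)
  expect_lt(sd(dt$truth$angles$left_knee), 5)
  expect_length(dt$truth$cycle_boundaries, 0)
})

test_that("pole plants are synchronous (DP), alternating (DS), absent (DT)", {
  tipz <- function(g, side) keypoint_track(g$sequence,
                                           paste0(side, "_pole_tip"), "z")
  dp <- generate_sequence(sim_config("DP"))
  expect_equal(tipz(dp, "left"), tipz(dp, "right"))
  expect_true(any(tipz(dp, "left") == 0))         # ground contact happens
  ds <- generate_sequence(sim_config("DS"))
  both_down <- (tipz(ds, "left") == 0) & (tipz(ds, "right") == 0)
  expect_lt(mean(both_down), 0.05)                # never planted together
  dt <- generate_sequence(sim_config("DT"))
  expect_true(all(tipz(dt, "left") > 0))
})

test_that("bone lengths are conserved across frames", {
  for (act in c("DP", "DS", "DT")) {
    g <- generate_sequence(sim_config(act, duration_s = 3))
    co <- g$sequence$coords
    pairs <- list(c("left_shoulder", "left_elbow"),
                  c("left_elbow", "left_wrist"),
                  c("right_hip", "right_knee"),
                  c("right_knee", "right_ankle"),
                  c("neck", "head"))
    for (p in pairs) {
      d <- sqrt(rowSums((co[, p[1], ] - co[, p[2], ])^2))
      expect_lt(diff(range(d)), 1e-9)
    }
  }
})

test_that("zero-lag elbow correlation separates the classes by construction", {
  zl <- function(act) {
    a <- generate_sequence(sim_config(act))$truth$angles
    cor(a$left_elbow - mean(a$left_elbow),
        a$right_elbow - mean(a$right_elbow))
  }
  expect_gt(zl("DP"), 0.99)
  expect_lt(zl("DS"), -0.99)
})

test_that("corruption is the identity at zero noise and zero dropout", {
  cfg <- sim_config("DP", duration_s = 2, noise_sd = 0, dropout_p = 0)
  g <- generate_sequence(cfg)
  cor <- corrupt(g$sequence, cfg)
  expect_identical(cor$sequence$coords, g$sequence$coords)
  expect_false(any(cor$dropout))
})

test_that("dropout count obeys the binomial bound and reproduces by seed", {
  cfg <- sim_config("DP", duration_s = 5, dropout_p = 0.1, seed = 21)
  g <- generate_sequence(cfg)   # 300 frames x 19 keypoints = 5700 slots
  c1 <- corrupt(g$sequence, cfg)
  c2 <- corrupt(g$sequence, cfg)
  expect_identical(c1$dropout, c2$dropout)
  n_slots <- prod(dim(c1$dropout))
  expect_lt(abs(sum(c1$dropout) - 0.1 * n_slots),
            3 * sqrt(n_slots * 0.1 * 0.9))
})

test_that("injected jitter has the configured standard deviation", {
  cfg <- sim_config("DS", duration_s = 10, noise_sd = 2, dropout_p = 0,
                    seed = 22)
  g <- generate_sequence(cfg)
  cor <- corrupt(g$sequence, cfg)
  res <- as.numeric(cor$sequence$coords - g$sequence$coords)
  expect_gte(length(res), 1e4)
  expect_gt(sd(res), 1.8)
  expect_lt(sd(res), 2.2)
})

test_that("pinhole projection follows similar triangles", {
  sch <- ski_schema()
  co <- array(0, c(1, 19, 3))
  co[1, , 1] <- 0; co[1, , 2] <- 0; co[1, , 3] <- 0
  co[1, 2, ] <- c(30, 0, 0)    # lateral-free point forward of the center
  s <- pose_sequence(co, 60, sch)
  p1 <- project_to_2d(s, focal = 1000, distance = 400, center = c(0, 0))
  expect_equal(p1$coords[1, 1, 1], 0)                    # optical axis
  expect_equal(p1$coords[1, 1, 2], 0)
  p2 <- project_to_2d(s, focal = 1000, distance = 800, center = c(0, 0))
  expect_equal(p1$coords[1, 2, 1] / p2$coords[1, 2, 1], 2, tolerance = 1e-12)
  s$coords[1, 1, 2] <- 500     # behind the camera
  expect_error(project_to_2d(s, distance = 400), "projection error")
})

test_that("projected ankle trajectories still segment into the true cycles", {
  g <- generate_sequence(sim_config("DS", phase = 0.8))
  p <- project_to_2d(g$sequence)
  expect_equal(p$dims, 2)
  sr <- segment_sequence(p)
  expect_length(sr$valleys, length(g$truth$cycle_boundaries))
})

test_that("corpus generation hits the requested counts deterministically", {
  c1 <- generate_dataset(c(DP = 3, DS = 2, DT = 2), seed = 9,
                         duration_s = 2)
  expect_length(c1$sequences, 7)
  expect_equal(as.numeric(table(c1$manifest$label)[c("DP", "DS", "DT")]),
               c(3, 2, 2))
  c2 <- generate_dataset(c(DP = 3, DS = 2, DT = 2), seed = 9,
                         duration_s = 2)
  expect_identical(c1$manifest, c2$manifest)
  expect_identical(c1$sequences[[1]]$sequence$coords,
                   c2$sequences[[1]]$sequence$coords)
  c3 <- generate_dataset(c(DP = 3, DS = 2, DT = 2), seed = 10,
                         duration_s = 2)
  expect_true(all(c1$manifest$cycle_frequency != c3$manifest$cycle_frequency))
  expect_true(all(c1$manifest$phase != c3$manifest$phase))
})

test_that("simulator rejects invalid configurations", {
  expect_error(sim_config("XX"), "arg")
  expect_error(sim_config("DP", dropout_p = 1), "dropout_p")
  expect_error(sim_config("DP", elbow_range = c(100, 190)), "angle ranges")
})
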