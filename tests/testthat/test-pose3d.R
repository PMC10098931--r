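rot_x <- function(a) matrix(c(1, 0, 0, 0, cos(a), -sin(a), 0, sin(a), cos(a)),
                            3, 3, byrow = TRUE)
rot_y <- function(a) matrix(c(cos(a), 0, sin(a), 0, 1, 0, -sin(a), 0, cos(a)),
                            3, 3, byrow = TRUE)
rot_z <- function(a) matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1),
                            3, 3, byrow = TRUE)

test_that("rotation_matrix composes x, y, z elementals and is orthonormal", {
  expect_equal(rotation_matrix(0, 0, 0), diag(3))
  half_x <- rotation_matrix(pi, 0, 0)
  expect_equal(as.numeric(half_x %*% c(0, 1, 0)), c(0, -1, 0))
  set.seed(1)
  for (i in 1:40) {
    a <- runif(3, -pi, pi)
    R <- rotation_matrix(a[1], a[2], a[3])
    expect_equal(R, rot_x(a[1]) %*% rot_y(a[2]) %*% rot_z(a[3]),
                 tolerance = 1e-14)
    expect_equal(t(R) %*% R, diag(3), tolerance = 1e-12)
    expect_equal(det(R), 1, tolerance = 1e-12)
  }
})

test_that("rotation loss is the mean squared Frobenius distance", {
  Rs <- list(rotation_matrix(0.1, 0.2, 0.3))
  expect_equal(rotation_loss(Rs, Rs), 0)
  expect_equal(rotation_loss(list(diag(3)), list(rot_x(pi))), 8)
  set.seed(2)
  preds <- lapply(1:6, function(i) matrix(rnorm(9), 3))
  truths <- lapply(1:6, function(i) matrix(rnorm(9), 3))
  acc <- 0
  for (i in 1:6) acc <- acc + sum((preds[[i]] - truths[[i]])^2)
  expect_equal(rotation_loss(preds, truths), acc / 6, tolerance = 1e-12)
  expect_error(rotation_loss(preds, truths[1:2]), "aligned")
})

test_that("3D location loss is the mean squared offset norm", {
  expect_equal(location_loss_3d(list(c(0, 0, 0), c(0, 0, 0))), 0)
  expect_equal(location_loss_3d(list(c(1, 0, 0))), 1.0)
  set.seed(3)
  offs <- lapply(1:9, function(i) rnorm(3))
  expect_equal(location_loss_3d(offs),
               mean(vapply(offs, function(o) sum(o^2), 1)),
               tolerance = 1e-12)
  expect_equal(total_3d_loss(0, 0), 0)
  expect_equal(total_3d_loss(1.5, 2.5), 4.0)
  expect_error(total_3d_loss(-1, 0), "non-negative")
})

test_that("midpoint fill recovers stationary and linear tracks", {
  s <- toy_sequence(n = 5, dims = 3, seed = 4)
  s$coords[, 1, 1] <- c(4, 4, NA, 4, 4)
  s$coords[, 1, 2] <- c(0, 0, NA, 2, 2)
  s$coords[, 1, 3] <- c(0, 1, NA, 3, 4)
  got <- fill_missing_midpoint(s, 2, "left_ankle")
  expect_equal(unname(got), c(4, 1, 2))
  # the halved-difference audit form returns 0 for a stationary point
  strict <- fill_missing_midpoint(s, 2, "left_ankle",
                                  strict_halved_difference = TRUE)
  expect_equal(unname(strict), c(0, 1, 1))
  s$coords[1:3, 2, ] <- NA
  expect_error(fill_missing_midpoint(s, 1, "right_ankle"), "gap-fill error")
})

test_that("least-squares fill reproduces linear motion exactly", {
  s <- toy_sequence(n = 20, dims = 3, seed = 5)
  truth <- 3 + 0.7 * (0:19)
  for (d in 1:3) s$coords[, 1, d] <- truth * d
  s$coords[9:11, 1, ] <- NA
  got <- fill_missing_least_squares(s, 8:10, "left_ankle", window = 5)
  for (d in 1:3) expect_equal(got[, d], truth[9:11] * d, tolerance = 1e-9)
  # constant track fills constant
  s2 <- toy_sequence(n = 20, dims = 2, seed = 6)
  s2$coords[, 1, ] <- 2.5
  s2$coords[5:6, 1, ] <- NA
  got2 <- fill_missing_least_squares(s2, 4:5, "left_ankle")
  expect_equal(as.numeric(got2), rep(2.5, 4), tolerance = 1e-9)
  s2$coords[1:10, 1, 1] <- NA
  expect_error(fill_missing_least_squares(s2, 4:5, "left_ankle"),
               "gap-fill error")
})

test_that("noisy linear track is restored within 1.5x the noise sd", {
  set.seed(7)
  rmse_all <- replicate(20, {
    n <- 60
    s <- toy_sequence(n = n, dims = 3)
    truth <- 10 + 1.5 * (0:(n - 1))
    noise_sd <- 2
    for (d in 1:3) s$coords[, 1, d] <- truth + rnorm(n, 0, noise_sd)
    gap <- 30:32
    s$coords[gap + 1, 1, ] <- NA
    got <- fill_missing_least_squares(s, gap, "left_ankle", window = 5)
    sqrt(mean((got - truth[gap + 1])^2))
  })
  expect_lt(mean(rmse_all), 1.5 * 2)
})

test_that("fill_gaps never alters observed frames", {
  cfg <- sim_config("DS", duration_s = 4, dropout_p = 0.1, noise_sd = 0,
                    seed = 9)
  gen <- generate_sequence(cfg)
  cor <- corrupt(gen$sequence, cfg)
  filled <- fill_gaps(cor$sequence)
  obs <- !missing_mask(cor$sequence)
  for (d in 1:3) {
    a <- cor$sequence$coords[, , d][obs]
    b <- filled$coords[, , d][obs]
    expect_identical(a, b)
  }
})

test_that("joint_angle gives textbook angles and rigid-motion invariance", {
  expect_equal(joint_angle(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0)), 90)
  expect_equal(joint_angle(c(-1, 0, 0), c(0, 0, 0), c(1, 0, 0)), 180)
  expect_error(joint_angle(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0)),
               "degenerate")
  set.seed(8)
  for (i in 1:30) {
    a1 <- rnorm(3); a2 <- rnorm(3); a3 <- rnorm(3)
    base <- joint_angle(a1, a2, a3)
    ang <- runif(3, -pi, pi)
    R <- rotation_matrix(ang[1], ang[2], ang[3])
    shift <- rnorm(3)
    scl <- runif(1, 0.1, 10)
    tr <- function(p) as.numeric(R %*% (scl * p) + shift)
    expect_equal(joint_angle(tr(a1), tr(a2), tr(a3)), base,
                 tolerance = 1e-9)
  }
})

test_that("angle series reflect the technique phase logic", {
  static <- generate_sequence(sim_config("DT", cycle_frequency = 0,
                                         duration_s = 2))
  a0 <- angle_series(static$sequence)
  expect_lt(diff(range(a0$left_elbow)), 1e-9)

  dp <- angle_series(generate_sequence(sim_config("DP"))$sequence)
  expect_equal(dp$left_elbow, dp$right_elbow, tolerance = 1e-9)

  ds <- angle_series(generate_sequence(sim_config("DS"))$sequence)
  le <- ds$left_elbow - mean(ds$left_elbow)
  re <- ds$right_elbow - mean(ds$right_elbow)
  expect_lt(cor(le, re), -0.99)     # anti-phase at zero lag
  half <- round(60 / (2 * 0.9))     # half a period in frames
  n <- length(le)
  expect_gt(cor(le[(half + 1):n], re[1:(n - half)]), 0.99)
})

test_that("angles propagate missingness instead of failing", {
  g <- generate_sequence(sim_config("DP", duration_s = 2))
  s <- g$sequence
  s$coords[10, "left_elbow", ] <- NA
  a <- angle_series(s)
  expect_true(is.na(a$left_elbow[10]))
  expect_false(anyNA(a$right_elbow))
})
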