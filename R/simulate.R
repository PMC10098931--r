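#' @name synthetic
#' @title Parametric simulator of 3D skiing kinematics
#'
#' @description
#' Generates clean 3D skeleton-plus-pole-tip trajectories with complete
#' ground truth for the three sub-techniques, so every pipeline stage can
#' be validated without external data. Joint angles follow sinusoidal
#' templates in angle space, mapped to positions through a fixed-
#' proportion two-segment limb model, which guarantees constant bone
#' lengths. The left/right phase offset realizes the technique logic:
#' 0 for double poling (bilateral, poles plant together), pi for diagonal
#' striding (contralateral alternation), near-zero amplitude for the
#' downhill tuck (static crouch, poles never planted). Detector
#' imperfections are emulated separately by [corrupt()]: i.i.d. Gaussian
#' coordinate jitter and random key-point dropout.
#'
#' Coordinates are pixels in a world frame: x forward (direction of
#' travel), y lateral (left positive), z vertical up. [project_to_2d()]
#' renders the side view a trackside camera sees.
NULL

#' Simulator configuration
#'
#' Angle ranges are `c(lo, hi)` degrees: the template oscillates about
#' their midpoint with half-range amplitude. Defaults follow the
#' technique taxonomy: full elbow/knee excursion for DP and DS, a nearly
#' frozen crouch (85 +/- 3 deg elbow, 100 +/- 3 deg knee) for DT.
#'
#' @param action `"DP"`, `"DS"` or `"DT"`.
#' @param fs frame rate in Hz (default 60).
#' @param duration_s sequence length in seconds.
#' @param cycle_frequency limb-cycle frequency in Hz (default 0.9).
#' @param elbow_range,knee_range joint-angle ranges in degrees.
#' @param forward_speed mean forward speed in px/frame.
#' @param noise_sd coordinate jitter standard deviation in px (used by
#'   [corrupt()]).
#' @param dropout_p per-(frame, key point) dropout probability.
#' @param phase initial phase in radians.
#' @param amp_scale multiplier on all oscillation amplitudes.
#' @param seed integer seed (used by [corrupt()]).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(action = c("DP", "DS", "DT"), fs = 60,
                       duration_s = 10, cycle_frequency = 0.9,
                       elbow_range = NULL, knee_range = NULL,
                       forward_speed = 2, noise_sd = 2, dropout_p = 0.02,
                       phase = 0, amp_scale = 1, seed = 1) {
  action <- match.arg(action)
  if (fs < 50) warning("frame rate below the recommended 50 Hz")
  if (dropout_p < 0 || dropout_p >= 1) stop("dropout_p must lie in [0, 1)")
  if (is.null(elbow_range)) {
    elbow_range <- if (action == "DT") c(82, 88) else c(60, 160)
  }
  if (is.null(knee_range)) {
    knee_range <- if (action == "DT") c(97, 103) else c(90, 160)
  }
  for (rg in list(elbow_range, knee_range)) {
    if (rg[1] < 0 || rg[2] > 180 || rg[1] > rg[2]) {
      stop("angle ranges must be increasing within [0, 180]")
    }
  }
  structure(list(action = action, fs = fs, duration_s = duration_s,
                 cycle_frequency = cycle_frequency,
                 elbow_range = elbow_range, knee_range = knee_range,
                 forward_speed = forward_speed, noise_sd = noise_sd,
                 dropout_p = dropout_p, phase = phase,
                 amp_scale = amp_scale, seed = seed),
            class = "sim_config")
}

# Fixed body proportions (px) and technique-specific posture parameters.
# Double poling is pole-propelled: the legs bob with a small stride while
# the arms drive; diagonal striding has a large leg stride; the tuck is a
# deep static crouch. The stride amplitudes are simulator choices, not
# physiological claims.
ski_body <- function(action) {
  list(thigh = 45, shank = 45, upper_arm = 32, forearm = 30,
       trunk = 55, head = 14, half_pelvis = 12, half_shoulders = 19,
       pole_lateral = 25, pole_height = 40,
       trunk_lean = switch(action, DP = 30, DS = 15, DT = 55) * pi / 180,
       thigh_amp = switch(action, DP = 8, DS = 25, DT = 1.5) * pi / 180,
       thigh_mid = 10 * pi / 180,
       arm_amp = switch(action, DP = 25, DS = 20, DT = 1.5) * pi / 180,
       arm_mid = 15 * pi / 180,
       hip_height = switch(action, DP = 92, DS = 95, DT = 70))
}

deg2rad <- function(d) d * pi / 180

# Left-ankle forward offset (relative to the hip) as a function of leg
# phase; used both in construction and to place true cycle boundaries.
ankle_forward_offset <- function(p, body, knee_mid, knee_amp) {
  gam <- body$thigh_mid + body$thigh_amp * cos(p)
  thk <- knee_mid + knee_amp * sin(p)
  del <- gam - (pi - thk)
  body$thigh * sin(gam) + body$shank * sin(del)
}

#' Generate one clean 3D sequence with ground truth
#'
#' Deterministic given the configuration. Returns the clean sequence and
#' a ground-truth record: the true coordinates, true joint-angle series,
#' true cycle-boundary frames (the per-cycle minima of the detrended
#' left-ankle forward coordinate, strictly interior), and the action
#' label. DT sequences have no cycle boundaries.
#'
#' @param cfg a [sim_config()].
#' @param schema a [ski_schema()] using the default key-point taxonomy.
#' @return list with `sequence` (clean 3D [pose_sequence()]) and `truth`.
#' @export
generate_sequence <- function(cfg, schema = ski_schema()) {
  stopifnot(inherits(cfg, "sim_config"))
  body <- ski_body(cfg$action)
  n <- round(cfg$duration_s * cfg$fs)
  t <- seq_len(n) - 1L
  f <- cfg$cycle_frequency
  phi <- 2 * pi * f * t / cfg$fs + cfg$phase
  # left/right phase offsets by technique
  side_off <- switch(cfg$action, DP = 0, DS = pi, DT = 0)
  amp <- cfg$amp_scale
  elbow_mid <- deg2rad(mean(cfg$elbow_range))
  elbow_amp <- amp * deg2rad(diff(cfg$elbow_range) / 2)
  knee_mid <- deg2rad(mean(cfg$knee_range))
  knee_amp <- amp * deg2rad(diff(cfg$knee_range) / 2)
  body$thigh_amp <- body$thigh_amp * amp
  body$arm_amp <- body$arm_amp * amp

  arm_p <- list(left = phi, right = phi + side_off)
  # contralateral gait for DS: left leg moves with the right arm
  leg_lag <- if (cfg$action == "DS") pi else 0
  leg_p <- list(left = phi + leg_lag, right = phi + leg_lag + side_off)

  X <- cfg$forward_speed * t
  coords <- array(NA_real_, c(n, length(schema$keypoints), 3))
  set_kp <- function(name, x, y, z) {
    ki <- match(name, schema$keypoints)
    coords[, ki, 1] <<- x; coords[, ki, 2] <<- y; coords[, ki, 3] <<- z
  }
  zhip <- body$hip_height
  lean <- body$trunk_lean
  set_kp("mid_hip", X, 0, zhip)
  set_kp("left_hip", X, body$half_pelvis, zhip)
  set_kp("right_hip", X, -body$half_pelvis, zhip)
  neck_x <- X + body$trunk * sin(lean)
  neck_z <- zhip + body$trunk * cos(lean)
  set_kp("neck", neck_x, 0, neck_z)
  head_x <- neck_x + body$head * sin(lean)
  head_z <- neck_z + body$head * cos(lean)
  set_kp("head", head_x, 0, head_z)
  set_kp("left_temple", head_x, 6, head_z)
  set_kp("right_temple", head_x, -6, head_z)

  angles <- data.frame(frame = t)
  for (side in c("left", "right")) {
    sgn <- if (side == "left") 1 else -1
    sh_x <- neck_x; sh_y <- sgn * body$half_shoulders; sh_z <- neck_z
    set_kp(paste0(side, "_shoulder"), sh_x, sh_y, sh_z)
    # arm: upper-arm swing about the shoulder, elbow flexion in plane
    alp <- body$arm_mid + body$arm_amp * cos(arm_p[[side]] - pi / 2)
    the <- elbow_mid + elbow_amp * cos(arm_p[[side]])
    el_x <- sh_x + body$upper_arm * sin(alp)
    el_z <- sh_z - body$upper_arm * cos(alp)
    bet <- alp + (pi - the)     # forearm flexes forward
    wr_x <- el_x + body$forearm * sin(bet)
    wr_z <- el_z - body$forearm * cos(bet)
    set_kp(paste0(side, "_elbow"), el_x, sh_y, el_z)
    set_kp(paste0(side, "_wrist"), wr_x, sh_y, wr_z)
    angles[[paste0(side, "_elbow")]] <- the * 180 / pi
    # leg: thigh swing about the hip, knee flexion lagging quarter-cycle
    gam <- body$thigh_mid + body$thigh_amp * cos(leg_p[[side]])
    thk <- knee_mid + knee_amp * sin(leg_p[[side]])
    del <- gam - (pi - thk)
    hip_y <- sgn * body$half_pelvis
    kn_x <- X + body$thigh * sin(gam)
    kn_z <- zhip - body$thigh * cos(gam)
    an_x <- kn_x + body$shank * sin(del)
    an_z <- kn_z - body$shank * cos(del)
    set_kp(paste0(side, "_knee"), kn_x, hip_y, kn_z)
    set_kp(paste0(side, "_ankle"), an_x, hip_y, an_z)
    angles[[paste0(side, "_knee")]] <- thk * 180 / pi
    # pole tip: grounded (z = 0) during the plant half-cycle for DP/DS,
    # held clear of the snow throughout for DT
    if (cfg$action == "DT") {
      tip_z <- rep(body$pole_height, n)
    } else {
      tip_z <- body$pole_height * pmax(0, sin(arm_p[[side]]))
    }
    set_kp(paste0(side, "_pole_tip"), wr_x + 10, sgn * body$pole_lateral,
           tip_z)
  }

  seq_out <- pose_sequence(coords, cfg$fs, schema)
  boundaries <- integer(0)
  if (cfg$action != "DT" && body$thigh_amp + knee_amp > 0) {
    grid <- seq(0, 2 * pi, length.out = 2001)[-2001]
    pstar <- grid[which.min(ankle_forward_offset(grid, body, knee_mid,
                                                 knee_amp))]
    off <- cfg$phase + leg_lag
    ks <- seq(floor((off - pstar) / (2 * pi)) - 2,
              length.out = ceiling(f * n / cfg$fs) + 5)
    tb <- (pstar - off + 2 * pi * ks) / (2 * pi * f) * cfg$fs
    # a landing only counts as a cycle boundary when enough trajectory is
    # in view on each side for its valley to realize the standard 10%-of-
    # range prominence; the required context follows from the waveform
    Pg <- ankle_forward_offset(grid, body, knee_mid, knee_amp)
    Rg <- diff(range(Pg))
    climb <- function(direction) {
      dphi <- (grid[which(ankle_forward_offset(pstar + direction * grid,
                                               body, knee_mid, knee_amp) >=
                            min(Pg) + 0.1 * Rg)])[1]
      dphi / (2 * pi * f) * cfg$fs
    }
    mL <- climb(-1); mR <- climb(+1)
    tb <- round(tb[tb >= mL & tb <= n - 1 - mR])
    boundaries <- as.integer(tb)
  }
  truth <- list(coords = coords, angles = angles,
                cycle_boundaries = boundaries,
                n_cycles = max(0L, length(boundaries) - 1L),
                action = cfg$action, config = cfg)
  list(sequence = seq_out, truth = truth)
}

#' Corrupt a clean sequence with jitter and dropout
#'
#' Adds i.i.d. Gaussian noise (`noise_sd`) to every coordinate and drops
#' each (frame, key point) observation independently with probability
#' `dropout_p`, reproducibly for a given seed. The dropout log is the
#' ground truth for [missing_mask()].
#'
#' @param seq a clean [pose_sequence()].
#' @param cfg a [sim_config()] supplying `noise_sd`, `dropout_p`, `seed`.
#' @return list with `sequence` (corrupted) and `dropout` (logical
#'   `n_frames x n_keypoints` matrix of injected dropouts).
#' @export
corrupt <- function(seq, cfg) {
  stopifnot(inherits(seq, "pose_sequence"), inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  coords <- seq$coords
  if (cfg$noise_sd > 0) {
    coords <- coords + stats::rnorm(length(coords), 0, cfg$noise_sd)
  }
  nf <- dim(coords)[1]; nk <- dim(coords)[2]
  drop <- matrix(stats::runif(nf * nk) < cfg$dropout_p, nf, nk)
  for (d in seq_len(dim(coords)[3])) {
    coords[, , d][drop] <- NA_real_
  }
  out <- pose_sequence(coords, seq$frame_rate, seq$schema)
  list(sequence = out, dropout = drop)
}

#' Pinhole projection to a trackside 2D view
#'
#' Renders the side view of a camera at lateral distance `distance` from
#' the track (optical axis along -y, i.e. perpendicular to the direction
#' of travel), with focal length `focal` in px. Image x grows with world
#' x; image y grows downward (so a rising point moves to smaller image
#' y). Points are projected about the sequence's mid trajectory so the
#' skier stays in frame.
#'
#' @param seq a 3D [pose_sequence()].
#' @param focal focal length in px.
#' @param distance camera distance in world units (> max lateral offset).
#' @param center world `c(x, z)` mapped to the principal point; default
#'   the mid-trajectory centroid.
#' @return a 2D [pose_sequence()].
#' @export
project_to_2d <- function(seq, focal = 1200, distance = 400, center = NULL) {
  stopifnot(inherits(seq, "pose_sequence"))
  if (seq$dims != 3) stop("projection needs a 3D sequence")
  depth <- distance - seq$coords[, , 2]
  if (any(depth[!is.na(depth)] <= 0)) {
    stop("projection error: non-positive depth (camera inside the scene)")
  }
  if (is.null(center)) {
    center <- c(mean(seq$coords[, , 1], na.rm = TRUE),
                mean(seq$coords[, , 3], na.rm = TRUE))
  }
  nf <- dim(seq$coords)[1]; nk <- dim(seq$coords)[2]
  coords <- array(NA_real_, c(nf, nk, 2))
  coords[, , 1] <- focal * (seq$coords[, , 1] - center[1]) / depth
  coords[, , 2] <- -focal * (seq$coords[, , 3] - center[2]) / depth
  pose_sequence(coords, seq$frame_rate, seq$schema, seq$confidence)
}

#' Generate a labeled synthetic corpus
#'
#' Draws `counts[cls]` sequences per class. Each sequence perturbs the
#' base configuration -- cycle frequency +/-15%, oscillation amplitude
#' +/-10%, forward speed +/-15%, uniform -- and starts at a random phase
#' (clips begin mid-cycle), then is corrupted with jitter and dropout.
#' Fully deterministic given `seed`.
#'
#' @param counts named integer vector, e.g. `c(DP = 79, DS = 66, DT = 75)`.
#' @param seed corpus seed.
#' @param fs,duration_s,cycle_frequency,forward_speed,noise_sd,dropout_p
#'   base simulator parameters (see [sim_config()]).
#' @return list of class `ski_corpus`: `sequences` (list of entries with
#'   `sequence`, `clean`, `truth`, `label`) and `manifest` (data frame of
#'   the drawn parameters).
#' @export
generate_dataset <- function(counts = c(DP = 79, DS = 66, DT = 75),
                             seed = 42, fs = 60, duration_s = 10,
                             cycle_frequency = 0.9, forward_speed = 2,
                             noise_sd = 2, dropout_p = 0.02) {
  stopifnot(all(counts >= 1), !is.null(names(counts)))
  set.seed(seed)
  entries <- list()
  manifest <- NULL
  id <- 0L
  for (cls in names(counts)) {
    for (i in seq_len(counts[[cls]])) {
      id <- id + 1L
      freq_i <- cycle_frequency * stats::runif(1, 0.85, 1.15)
      amp_i <- stats::runif(1, 0.90, 1.10)
      speed_i <- forward_speed * stats::runif(1, 0.85, 1.15)
      phase_i <- stats::runif(1, 0, 2 * pi)
      seed_i <- sample.int(.Machine$integer.max, 1)
      cfg <- sim_config(cls, fs = fs, duration_s = duration_s,
                        cycle_frequency = freq_i, forward_speed = speed_i,
                        noise_sd = noise_sd, dropout_p = dropout_p,
                        phase = phase_i, amp_scale = amp_i, seed = seed_i)
      gen <- generate_sequence(cfg)
      cor <- corrupt(gen$sequence, cfg)
      entries[[id]] <- list(sequence = cor$sequence, clean = gen$sequence,
                            truth = gen$truth, dropout = cor$dropout,
                            label = cls)
      manifest <- rbind(manifest,
                        data.frame(id = id, label = cls,
                                   cycle_frequency = freq_i,
                                   amp_scale = amp_i, speed = speed_i,
                                   phase = phase_i, seed = seed_i))
    }
  }
  structure(list(sequences = entries, manifest = manifest, seed = seed),
            class = "ski_corpus")
}

#' @export
print.ski_corpus <- function(x, ...) {
  cat("Synthetic ski corpus:", length(x$sequences), "sequences (",
      paste(names(table(x$manifest$label)), table(x$manifest$label),
            sep = "=", collapse = ", "), ") seed", x$seed, "\n")
  invisible(x)
}
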