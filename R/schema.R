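#' Skeleton schema for markerless skiing pose data
#'
#' A schema names the tracked key points and the structural relations the
#' rest of the toolkit needs: which points form left/right pairs, which
#' ordered triplets define joint angles (proximal, vertex, distal), and
#' which points are ski-pole tips rather than anatomical landmarks.
#'
#' The default schema has 17 body points -- seven bilateral pairs (temple,
#' shoulder, elbow, wrist, hip, knee, ankle) plus head, neck and mid-hip --
#' and the two pole-tip points, 19 in all. Any other taxonomy can be
#' supplied as long as every id referenced by pairs, triplets or pole tips
#' is a declared key point.
#'
#' @param keypoints character vector of unique key-point identifiers.
#' @param bilateral_pairs list of length-2 character vectors `c(left, right)`.
#' @param angle_triplets named list of length-3 character vectors
#'   `c(proximal, vertex, distal)`; the name labels the angle series.
#' @param pole_tips character vector of pole-tip identifiers (may be empty).
#' @return An object of class `ski_schema`.
#' @examples
#' sch <- ski_schema()
#' length(sch$keypoints)   # 19
#' @export
ski_schema <- function(keypoints = default_keypoints(),
                       bilateral_pairs = default_bilateral_pairs(),
                       angle_triplets = default_angle_triplets(),
                       pole_tips = c("left_pole_tip", "right_pole_tip")) {
  keypoints <- as.character(keypoints)
  if (anyDuplicated(keypoints)) {
    stop("schema error: duplicated key-point identifiers")
  }
  check_ids <- function(ids, what) {
    bad <- setdiff(unlist(ids), keypoints)
    if (length(bad)) {
      stop("schema error: ", what, " references unknown key point(s): ",
           paste(bad, collapse = ", "))
    }
  }
  check_ids(bilateral_pairs, "bilateral_pairs")
  check_ids(angle_triplets, "angle_triplets")
  check_ids(pole_tips, "pole_tips")
  if (length(angle_triplets) && is.null(names(angle_triplets))) {
    stop("schema error: angle_triplets must be named")
  }
  structure(
    list(keypoints = keypoints,
         bilateral_pairs = bilateral_pairs,
         angle_triplets = angle_triplets,
         pole_tips = pole_tips),
    class = "ski_schema")
}

default_keypoints <- function() {
  c("head", "neck", "mid_hip",
    "left_temple", "right_temple",
    "left_shoulder", "right_shoulder",
    "left_elbow", "right_elbow",
    "left_wrist", "right_wrist",
    "left_hip", "right_hip",
    "left_knee", "right_knee",
    "left_ankle", "right_ankle",
    "left_pole_tip", "right_pole_tip")
}

default_bilateral_pairs <- function() {
  lapply(c("temple", "shoulder", "elbow", "wrist", "hip", "knee", "ankle"),
         function(p) c(paste0("left_", p), paste0("right_", p)))
}

default_angle_triplets <- function() {
  list(left_elbow  = c("left_shoulder", "left_elbow", "left_wrist"),
       right_elbow = c("right_shoulder", "right_elbow", "right_wrist"),
       left_knee   = c("left_hip", "left_knee", "left_ankle"),
       right_knee  = c("right_hip", "right_knee", "right_ankle"))
}

#' @export
print.ski_schema <- function(x, ...) {
  cat("Skeleton schema:", length(x$keypoints), "key points (",
      length(x$pole_tips), "pole tips ),",
      length(x$bilateral_pairs), "bilateral pairs,",
      length(x$angle_triplets), "angle triplets\n")
  invisible(x)
}

#' Pose sequence container
#'
#' A `pose_sequence` holds time-indexed key-point coordinates with
#' per-observation confidences. Coordinates are image pixels for 2D data
#' (origin top-left, x rightward, y downward) or arbitrary length units
#' for 3D data; frames are indexed from 0 in files and map to array rows
#' 1..n internally. Missing observations are `NA` (never magic numbers).
#'
#' @param coords numeric array `n_frames x n_keypoints x dims` (dims 2 or 3),
#'   with `NA` marking missing coordinates. Dimnames of the second margin,
#'   if present, must match the schema.
#' @param frame_rate sampling rate in Hz. Rates below 50 Hz are accepted
#'   with a warning: slower video undersamples poling cycles.
#' @param schema a [ski_schema()].
#' @param confidence optional `n_frames x n_keypoints` matrix in \[0, 1\].
#' @return An object of class `pose_sequence`.
#' @export
pose_sequence <- function(coords, frame_rate, schema = ski_schema(),
                          confidence = NULL) {
  if (length(dim(coords)) != 3L) {
    stop("coords must be a 3-d array (frames x keypoints x dims)")
  }
  dims <- dim(coords)[3]
  if (!dims %in% c(2L, 3L)) stop("dims must be 2 or 3")
  if (dim(coords)[2] != length(schema$keypoints)) {
    stop("schema error: coords has ", dim(coords)[2],
         " key points but schema declares ", length(schema$keypoints))
  }
  if (!is.numeric(frame_rate) || length(frame_rate) != 1L || frame_rate <= 0) {
    stop("frame_rate must be a positive scalar (Hz)")
  }
  if (frame_rate < 50) {
    warning("frame rate ", frame_rate,
            " Hz is below the recommended 50 Hz minimum")
  }
  if (any(is.infinite(coords))) {
    stop("coordinates must be finite or NA")
  }
  dimnames(coords) <- list(NULL, schema$keypoints,
                           c("x", "y", "z")[seq_len(dims)])
  if (is.null(confidence)) {
    confidence <- matrix(NA_real_, dim(coords)[1], dim(coords)[2])
  }
  confidence <- as.matrix(confidence)
  if (!all(dim(confidence) == dim(coords)[1:2])) {
    stop("confidence must be n_frames x n_keypoints")
  }
  cf <- confidence[is.finite(confidence)]
  if (length(cf) && (any(cf < 0) || any(cf > 1))) {
    stop("confidence values must lie in [0, 1]")
  }
  colnames(confidence) <- schema$keypoints
  structure(
    list(coords = coords, confidence = confidence,
         frame_rate = frame_rate, dims = dims, schema = schema),
    class = "pose_sequence")
}

#' @export
print.pose_sequence <- function(x, ...) {
  cat("Pose sequence:", n_frames(x), "frames,",
      length(x$schema$keypoints), "key points,",
      x$dims, "D at", x$frame_rate, "Hz (",
      sum(missing_mask(x)), "missing observations )\n")
  invisible(x)
}

#' Number of frames in a pose sequence
#' @param seq a [pose_sequence()].
#' @export
n_frames <- function(seq) dim(seq$coords)[1]

#' Missing-observation mask
#'
#' A key point counts as missing in a frame when any of its coordinates is
#' absent or its confidence falls below `conf_floor`. With the default
#' floor of 0 only genuinely absent coordinates are flagged.
#'
#' @param seq a [pose_sequence()].
#' @param conf_floor confidence threshold; observations with recorded
#'   confidence strictly below it are treated as missing.
#' @return logical `n_frames x n_keypoints` matrix.
#' @export
missing_mask <- function(seq, conf_floor = 0) {
  stopifnot(inherits(seq, "pose_sequence"))
  m <- is.na(seq$coords[, , 1, drop = FALSE])[, , 1]
  for (d in seq_len(seq$dims)[-1]) m <- m | is.na(seq$coords[, , d])
  low <- !is.na(seq$confidence) & seq$confidence < conf_floor
  mask <- m | low
  dim(mask) <- dim(seq$confidence)
  colnames(mask) <- seq$schema$keypoints
  mask
}

#' Extract one key point's coordinate track
#'
#' @param seq a [pose_sequence()].
#' @param keypoint key-point identifier.
#' @param coord one of `"x"`, `"y"`, `"z"`.
#' @return numeric vector of length `n_frames(seq)` with `NA` at missing frames.
#' @export
keypoint_track <- function(seq, keypoint, coord = "x") {
  stopifnot(inherits(seq, "pose_sequence"))
  if (!keypoint %in% seq$schema$keypoints) {
    stop("schema error: unknown key point '", keypoint, "'")
  }
  ci <- match(coord, c("x", "y", "z"))
  if (is.na(ci) || ci > seq$dims) stop("coordinate '", coord, "' not available")
  seq$coords[, keypoint, ci]
}

#' Read a pose sequence from CSV or JSON
#'
#' The CSV dialect is one row per (frame, key point) with header
#' `frame,keypoint,x,y[,z],confidence`; empty cells encode missing values
#' and frames are numbered from 0. The JSON dialect is the one written by
#' [write_pose_sequence()]: an object with `frame_rate`, `schema` and a
#' `frames` array whose elements map key-point id to `[x, y, (z), conf]`
#' with `null` for missing components. Absent (frame, key point) records
#' become missing entries; unknown key-point ids are rejected.
#'
#' @param path file path.
#' @param schema a [ski_schema()] the file must conform to.
#' @param frame_rate required for CSV input (the file carries none).
#' @param format `"csv"`, `"json"`, or `"auto"` (by file extension).
#' @return a [pose_sequence()].
#' @export
read_pose_sequence <- function(path, schema = ski_schema(),
                               frame_rate = NULL, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (format == "csv") {
    read_pose_csv(path, schema, frame_rate)
  } else {
    read_pose_json(path, schema)
  }
}

read_pose_csv <- function(path, schema, frame_rate) {
  if (is.null(frame_rate)) stop("frame_rate must be given for CSV input")
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, colClasses = NA),
    error = function(e) stop("parse error in ", path, ": ", conditionMessage(e)))
  need <- c("frame", "keypoint", "x", "y")
  if (!all(need %in% names(df))) {
    stop("parse error in ", path, ": header must contain ",
         paste(need, collapse = ","))
  }
  dims <- if ("z" %in% names(df)) 3L else 2L
  bad <- which(!df$keypoint %in% schema$keypoints)
  if (length(bad)) {
    stop("schema error at line ", bad[1] + 1L, ": unknown key point '",
         df$keypoint[bad[1]], "'")
  }
  if (nrow(df) == 0) {
    return(pose_sequence(array(NA_real_, c(0, length(schema$keypoints), dims)),
                         frame_rate, schema))
  }
  if (any(is.na(df$frame)) || any(df$frame != floor(df$frame)) || any(df$frame < 0)) {
    stop("parse error in ", path, ": frame indices must be non-negative integers")
  }
  nf <- max(df$frame) + 1L
  nk <- length(schema$keypoints)
  coords <- array(NA_real_, c(nf, nk, dims))
  conf <- matrix(NA_real_, nf, nk)
  fi <- df$frame + 1L
  ki <- match(df$keypoint, schema$keypoints)
  coords[cbind(fi, ki, 1L)] <- suppressWarnings(as.numeric(df$x))
  coords[cbind(fi, ki, 2L)] <- suppressWarnings(as.numeric(df$y))
  if (dims == 3L) coords[cbind(fi, ki, 3L)] <- suppressWarnings(as.numeric(df$z))
  if ("confidence" %in% names(df)) {
    conf[cbind(fi, ki)] <- suppressWarnings(as.numeric(df$confidence))
  }
  pose_sequence(coords, frame_rate, schema, conf)
}

read_pose_json <- function(path, schema) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                  error = function(e) stop("parse error in ", path, ": ",
                                           conditionMessage(e)))
  if (is.null(obj$frame_rate)) stop("parse error in ", path, ": no frame_rate")
  file_schema <- unlist(obj$schema)
  bad <- setdiff(file_schema, schema$keypoints)
  if (length(bad)) {
    stop("schema error: unknown key point(s) in file: ",
         paste(bad, collapse = ", "))
  }
  nf <- length(obj$frames)
  nk <- length(schema$keypoints)
  dims <- if (isTRUE(obj$dims == 3) || is.null(obj$dims) &&
              nf > 0 && any(lengths(obj$frames[[1]]) >= 4)) 3L else 2L
  if (!is.null(obj$dims)) dims <- as.integer(obj$dims)
  coords <- array(NA_real_, c(nf, nk, dims))
  conf <- matrix(NA_real_, nf, nk)
  null_na <- function(v) if (is.null(v)) NA_real_ else as.numeric(v)
  for (f in seq_len(nf)) {
    fr <- obj$frames[[f]]
    bad <- setdiff(names(fr), schema$keypoints)
    if (length(bad)) {
      stop("schema error at frame ", f - 1L, ": unknown key point '",
           bad[1], "'")
    }
    for (kp in names(fr)) {
      v <- fr[[kp]]
      ki <- match(kp, schema$keypoints)
      for (d in seq_len(dims)) coords[f, ki, d] <- null_na(v[[d]])
      if (length(v) >= dims + 1L) conf[f, ki] <- null_na(v[[dims + 1L]])
    }
  }
  pose_sequence(coords, as.numeric(obj$frame_rate), schema, conf)
}

#' Write a pose sequence to CSV or JSON
#'
#' JSON round-trips coordinates bit-identically (17 significant digits);
#' CSV round-trips to the printed precision. Missing values are written as
#' empty CSV cells or JSON `null`.
#'
#' @param seq a [pose_sequence()].
#' @param path output file path.
#' @param format `"csv"` or `"json"`.
#' @param digits significant digits for CSV output.
#' @return `path`, invisibly.
#' @export
write_pose_sequence <- function(seq, path, format = c("csv", "json"),
                                digits = 10) {
  stopifnot(inherits(seq, "pose_sequence"))
  format <- match.arg(format)
  if (format == "csv") {
    nf <- n_frames(seq)
    nk <- length(seq$schema$keypoints)
    fi <- rep(seq_len(nf), each = nk)
    ki <- rep(seq_len(nk), times = nf)
    df <- data.frame(frame = fi - 1L,
                     keypoint = seq$schema$keypoints[ki])
    fmt <- function(v) ifelse(is.na(v), "", formatC(v, digits = digits,
                                                    format = "g"))
    pick <- function(d) if (nf == 0) character(0) else
      fmt(seq$coords[cbind(fi, ki, d)])
    df$x <- pick(1L)
    df$y <- pick(2L)
    if (seq$dims == 3L) df$z <- pick(3L)
    df$confidence <- if (nf == 0) character(0) else
      fmt(seq$confidence[cbind(fi, ki)])
    ok <- tryCatch({
      utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
      TRUE
    }, error = function(e) FALSE)
    if (!ok) stop("I/O error: cannot write ", path)
  } else {
    frames <- lapply(seq_len(n_frames(seq)), function(f) {
      fr <- list()
      for (ki in seq_along(seq$schema$keypoints)) {
        v <- seq$coords[f, ki, ]
        cf <- seq$confidence[f, ki]
        if (all(is.na(v)) && is.na(cf)) next
        fr[[seq$schema$keypoints[ki]]] <- c(as.list(unname(v)), list(cf))
      }
      fr
    })
    obj <- list(frame_rate = seq$frame_rate, dims = seq$dims,
                schema = seq$schema$keypoints, frames = frames)
    ok <- tryCatch({
      jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                           null = "null", na = "null")
      TRUE
    }, error = function(e) FALSE)
    if (!ok) stop("I/O error: cannot write ", path)
  }
  invisible(path)
}
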