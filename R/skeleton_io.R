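#' Skeletal sequence container
#'
#' A `skeleton_sequence` holds the time-ordered joint-center stream of one
#' trial from one sensor: timestamps in seconds, an `n x j x 3` coordinate
#' array in millimetres (camera frame: x horizontal along the transfer
#' direction, y vertical up, z depth) and an `n x j` validity matrix flagging
#' tracked vs missing joints. Invalid joints keep an `NA` coordinate; frames
#' with partially missing joints are retained, never dropped.
#'
#' @param sensor A [sensor_model()] (or a sensor name).
#' @param timestamps Numeric vector, strictly increasing, seconds.
#' @param joints Character vector of joint names; each must belong to the
#'   sensor's vocabulary (matching is case-insensitive, underscores ignored).
#' @param xyz Numeric array `length(timestamps) x length(joints) x 3`, mm.
#' @param valid Logical matrix `length(timestamps) x length(joints)`; defaults
#'   to finite coordinates.
#' @param trial_id,subject_id Opaque labels carried through the pipeline.
#' @return A validated `skeleton_sequence`.
#' @export
skeleton_sequence <- function(sensor, timestamps, joints, xyz, valid = NULL,
                              trial_id = NA_character_,
                              subject_id = NA_character_) {
  if (!inherits(sensor, "sensor_model")) sensor <- sensor_model(sensor)
  timestamps <- as.numeric(timestamps)
  n <- length(timestamps)
  if (n < 2) stop("a skeleton sequence needs at least 2 frames", call. = FALSE)
  if (any(diff(timestamps) <= 0)) {
    stop("timestamps must be strictly increasing", call. = FALSE)
  }
  resolved <- match_joint(joints, sensor$joint_vocabulary)
  if (anyNA(resolved)) {
    stop(
      "joint name(s) not in the ", sensor$name, " vocabulary: ",
      paste(joints[is.na(resolved)], collapse = ", "),
      call. = FALSE
    )
  }
  if (anyDuplicated(resolved)) {
    stop("duplicated joint name(s): ",
         paste(unique(resolved[duplicated(resolved)]), collapse = ", "),
         call. = FALSE)
  }
  j <- length(resolved)
  xyz <- array(as.numeric(xyz), dim = c(n, j, 3))
  if (is.null(valid)) {
    valid <- apply(is.finite(xyz), c(1, 2), all)
  }
  valid <- matrix(as.logical(valid), n, j)
  valid[is.na(valid)] <- FALSE
  # tracked joints must have finite coordinates
  finite <- apply(is.finite(xyz), c(1, 2), all)
  valid <- valid & finite
  xyz[!rep(valid, 3)] <- NA_real_
  dimnames(xyz) <- list(NULL, resolved, c("x", "y", "z"))
  colnames(valid) <- resolved
  structure(
    list(
      sensor = sensor, timestamps = timestamps, joints = resolved,
      xyz = xyz, valid = valid,
      trial_id = trial_id, subject_id = subject_id
    ),
    class = "skeleton_sequence"
  )
}

#' @export
print.skeleton_sequence <- function(x, ...) {
  cat("<skeleton_sequence>", x$sensor$name,
      sprintf("| %d frames | %.2f-%.2f s | %d joints\n",
              length(x$timestamps), min(x$timestamps), max(x$timestamps),
              length(x$joints)))
  miss <- sum(!x$valid)
  if (miss > 0) cat("  missing joint observations:", miss, "\n")
  if (!is.na(x$trial_id)) cat("  trial:", x$trial_id, "\n")
  invisible(x)
}

#' Number of frames in a sequence
#' @param seq A `skeleton_sequence`.
#' @export
n_frames <- function(seq) length(seq$timestamps)

#' Extract one joint's trajectory
#'
#' @param seq A `skeleton_sequence`.
#' @param joint Joint name (vocabulary spelling, matched loosely).
#' @return An `n x 3` matrix in mm with `NA` rows where the joint is missing.
#' @export
joint_xyz <- function(seq, joint) {
  resolved <- match_joint(joint, seq$joints)
  if (is.na(resolved)) {
    stop("joint not present in sequence: ", joint, call. = FALSE)
  }
  m <- seq$xyz[, resolved, , drop = TRUE]
  matrix(m, ncol = 3, dimnames = list(NULL, c("x", "y", "z")))
}

# full-precision number formatting so CSV round-trips are bit-identical
fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- ""
  out
}

#' Write a skeletal recording to CSV
#'
#' Long format, one row per (frame, joint):
#' `timestamp,joint,x,y,z,valid`. Coordinates are written with 17 significant
#' digits so that [read_recording()] recovers the sequence bit-identically.
#' A `.gz` extension writes gzip-compressed output.
#'
#' @param seq A `skeleton_sequence`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(seq, path) {
  stopifnot(inherits(seq, "skeleton_sequence"))
  n <- n_frames(seq)
  j <- length(seq$joints)
  df <- data.frame(
    timestamp = fmt_num(rep(seq$timestamps, each = j)),
    joint = rep(seq$joints, times = n),
    x = fmt_num(as.vector(t(seq$xyz[, , 1]))),
    y = fmt_num(as.vector(t(seq$xyz[, , 2]))),
    z = fmt_num(as.vector(t(seq$xyz[, , 3]))),
    valid = as.vector(t(seq$valid)),
    stringsAsFactors = FALSE
  )
  if (!is.na(seq$trial_id)) df$trial_id <- seq$trial_id
  if (!is.na(seq$subject_id)) df$subject_id <- seq$subject_id
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  ok <- tryCatch(
    {
      utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
      TRUE
    },
    error = function(e) {
      stop("cannot write recording to ", path, ": ", conditionMessage(e),
           call. = FALSE)
    }
  )
  invisible(path)
}

#' Read a skeletal recording from CSV
#'
#' Accepts the canonical long format (`timestamp,joint,x,y,z[,valid]`) or a
#' wide format with one row per frame and `<joint>_x`, `<joint>_y`,
#' `<joint>_z` columns; the layout is auto-detected from the header. Gzip
#' input (`.gz`) is handled transparently. Rows with malformed numeric fields
#' are flagged missing, not dropped; a parse report with per-joint missing
#' counts is attached as attribute `"parse_report"`.
#'
#' @param path CSV file path.
#' @param sensor The declared [sensor_model()] for the recording. Joint names
#'   outside the sensor's vocabulary raise an error naming the offender.
#' @param trial_id,subject_id Optional labels; by default taken from matching
#'   columns if present.
#' @return A `skeleton_sequence`.
#' @export
read_recording <- function(path, sensor, trial_id = NULL, subject_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (!inherits(sensor, "sensor_model")) sensor <- sensor_model(sensor)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  header <- names(df)
  if (!"timestamp" %in% header) {
    stop("recording has no 'timestamp' column: ", path, call. = FALSE)
  }
  long <- all(c("joint", "x", "y", "z") %in% header)
  if (long) {
    seq <- parse_long_recording(df, sensor)
  } else {
    seq <- parse_wide_recording(df, sensor)
  }
  blank_na <- function(v) if (is.na(v) || !nzchar(v)) NA_character_ else v
  if (!is.null(trial_id)) seq$trial_id <- trial_id
  else if ("trial_id" %in% header) seq$trial_id <- blank_na(df$trial_id[1])
  if (!is.null(subject_id)) seq$subject_id <- subject_id
  else if ("subject_id" %in% header) {
    seq$subject_id <- blank_na(df$subject_id[1])
  }
  seq
}

as_num <- function(x) suppressWarnings(as.numeric(x))

parse_long_recording <- function(df, sensor) {
  joints <- unique(df$joint)
  resolved <- match_joint(joints, sensor$joint_vocabulary)
  if (anyNA(resolved)) {
    stop("joint name(s) not in the ", sensor$name, " vocabulary: ",
         paste(joints[is.na(resolved)], collapse = ", "), call. = FALSE)
  }
  ts_raw <- as_num(df$timestamp)
  if (anyNA(ts_raw)) stop("malformed timestamp field", call. = FALSE)
  timestamps <- unique(ts_raw)
  if (any(diff(timestamps) <= 0)) {
    stop("non-monotonic timestamps in recording", call. = FALSE)
  }
  n <- length(timestamps); j <- length(joints)
  xyz <- array(NA_real_, c(n, j, 3))
  valid <- matrix(FALSE, n, j)
  fi <- match(ts_raw, timestamps)
  ji <- match(df$joint, joints)
  xs <- as_num(df$x); ys <- as_num(df$y); zs <- as_num(df$z)
  declared <- if ("valid" %in% names(df)) {
    toupper(trimws(df$valid)) %in% c("TRUE", "T", "1")
  } else rep(TRUE, nrow(df))
  ok <- declared & !is.na(xs) & !is.na(ys) & !is.na(zs)
  idx <- cbind(fi, ji)
  xyz[cbind(idx, 1)] <- xs
  xyz[cbind(idx, 2)] <- ys
  xyz[cbind(idx, 3)] <- zs
  valid[idx] <- ok
  seq <- skeleton_sequence(sensor, timestamps, joints, xyz, valid)
  attach_parse_report(seq, declared_missing = sum(!ok))
}

parse_wide_recording <- function(df, sensor) {
  coord_cols <- grep("_(x|y|z)$", names(df), value = TRUE)
  if (length(coord_cols) == 0) {
    stop("unrecognized recording layout (no joint/x/y/z columns and no ",
         "<joint>_x columns)", call. = FALSE)
  }
  joints <- unique(sub("_(x|y|z)$", "", coord_cols))
  resolved <- match_joint(joints, sensor$joint_vocabulary)
  if (anyNA(resolved)) {
    stop("joint name(s) not in the ", sensor$name, " vocabulary: ",
         paste(joints[is.na(resolved)], collapse = ", "), call. = FALSE)
  }
  timestamps <- as_num(df$timestamp)
  if (anyNA(timestamps)) stop("malformed timestamp field", call. = FALSE)
  if (any(diff(timestamps) <= 0)) {
    stop("non-monotonic timestamps in recording", call. = FALSE)
  }
  n <- nrow(df); j <- length(joints)
  xyz <- array(NA_real_, c(n, j, 3))
  for (a in seq_along(joints)) {
    for (c3 in 1:3) {
      col <- paste0(joints[a], "_", c("x", "y", "z")[c3])
      if (col %in% names(df)) xyz[, a, c3] <- as_num(df[[col]])
    }
  }
  seq <- skeleton_sequence(sensor, timestamps, joints, xyz)
  attach_parse_report(seq, declared_missing = 0L)
}

attach_parse_report <- function(seq, declared_missing) {
  report <- list(
    n_frames = n_frames(seq),
    n_joints = length(seq$joints),
    missing_by_joint = colSums(!seq$valid),
    n_missing = sum(!seq$valid),
    declared_missing = declared_missing
  )
  attr(seq, "parse_report") <- report
  seq
}

#' Align two sequences on a common time base
#'
#' Matches frames of the two recordings by nearest timestamp using mutual
#' nearest neighbours: a pair (i, j) is kept when frame j of `b` is the
#' nearest neighbour of frame i of `a` and vice versa, and their timestamp
#' gap is at most `max_skew`. Mutual matching makes the pairing symmetric
#' (`align_pair(a, b)` and `align_pair(b, a)` produce the same pairs) and
#' never reuses a frame. Unmatched frames are excluded.
#'
#' @param a,b `skeleton_sequence` objects with overlapping time ranges.
#' @param max_skew Maximum timestamp gap in seconds for a valid pair;
#'   default is half the nominal frame period of `a`'s sensor.
#' @param offset Constant clock offset in seconds added to `b`'s timestamps
#'   before matching (for un-synchronized recording clocks); default 0.
#' @return A data frame with columns `idx_a`, `idx_b`, `t_a`, `t_b`, `dt`.
#' @export
align_pair <- function(a, b, max_skew = NULL, offset = 0) {
  stopifnot(inherits(a, "skeleton_sequence"), inherits(b, "skeleton_sequence"))
  if (is.null(max_skew)) max_skew <- 0.5 / a$sensor$nominal_rate
  ta <- a$timestamps
  tb <- b$timestamps + offset
  if (min(tb) > max(ta) || min(ta) > max(tb)) {
    stop("recordings do not overlap in time", call. = FALSE)
  }
  nb_of_a <- nearest_idx(tb, ta)   # for each a frame, nearest b frame
  na_of_b <- nearest_idx(ta, tb)   # for each b frame, nearest a frame
  ia <- seq_along(ta)
  mutual <- na_of_b[nb_of_a] == ia
  keep <- mutual & abs(ta - tb[nb_of_a]) <= max_skew + 1e-12
  out <- data.frame(
    idx_a = ia[keep],
    idx_b = nb_of_a[keep],
    t_a = ta[keep],
    t_b = b$timestamps[nb_of_a[keep]],
    dt = (ta - tb[nb_of_a])[keep]
  )
  if (nrow(out) == 0) {
    stop("no frame pairs within max_skew = ", max_skew, " s", call. = FALSE)
  }
  out
}

# index of the element of `grid` nearest to each element of `q`
nearest_idx <- function(grid, q) {
  lo <- findInterval(q, grid, all.inside = TRUE)
  hi <- pmin(lo + 1, length(grid))
  ifelse(abs(q - grid[lo]) <= abs(q - grid[hi]), lo, hi)
}
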