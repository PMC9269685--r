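#' Joint mapping from a sensor vocabulary to the canonical joint set
#'
#' Every feature in the pipeline is computed from five canonical joints:
#' `pelvis`, `spine_upper`, `shoulder_left`, `shoulder_right`, `elbow_left`
#' (the elbow of the leading arm). Each sensor maps onto these either
#' directly or through a derived joint:
#'
#' * Kinect V2: `pelvis <- SpineBase`, `spine_upper <- SpineShoulder`, both
#'   direct.
#' * Kinect Azure: `pelvis <- Pelvis`; the Azure has no joint matching the
#'   V2's SpineShoulder, so `spine_upper` is approximated as the midpoint of
#'   `ClavicleLeft` and `ClavicleRight`.
#' * RealSense/Nuitrack: `pelvis <- Waist`; `spine_upper` is taken as the
#'   midpoint of `LeftCollar` and `RightCollar`, by the same collar-midpoint
#'   rule used for the Azure. (Assumption: the Nuitrack vocabulary provides
#'   the two collar joints but no canonical combining rule; the symmetric
#'   midpoint is adopted and documented.)
#'
#' Shoulders and the elbow map by name. With `side = "right"` the transfer
#' leads with the right arm and the left/right mappings mirror: the
#' `shoulder_left`/`elbow_left` slots then carry the right-side joints so the
#' downstream features always see the leading arm in the same slots (angles
#' are unsigned, so mirroring does not change their definition).
#'
#' @param sensor A [sensor_model()] or sensor name.
#' @param side Leading side of the transfer, `"left"` (default) or `"right"`.
#' @return A `joint_mapping` object with `direct` (canonical -> source joint)
#'   and `derived` (canonical -> list(rule, sources)) entries; every canonical
#'   joint is produced exactly once.
#' @export
joint_mapping <- function(sensor, side = c("left", "right")) {
  if (!inherits(sensor, "sensor_model")) sensor <- sensor_model(sensor)
  side <- match.arg(side)
  m <- switch(sensor$name,
    KINECT_V2 = list(
      direct = c(
        pelvis = "SpineBase", spine_upper = "SpineShoulder",
        shoulder_left = "ShoulderLeft", shoulder_right = "ShoulderRight",
        elbow_left = "ElbowLeft", elbow_right = "ElbowRight"
      ),
      derived = list()
    ),
    KINECT_AZURE = list(
      direct = c(
        pelvis = "Pelvis",
        shoulder_left = "ShoulderLeft", shoulder_right = "ShoulderRight",
        elbow_left = "ElbowLeft", elbow_right = "ElbowRight"
      ),
      derived = list(
        spine_upper = list(rule = "midpoint",
                           sources = c("ClavicleLeft", "ClavicleRight"))
      )
    ),
    REALSENSE_NUITRACK = list(
      direct = c(
        pelvis = "Waist",
        shoulder_left = "LeftShoulder", shoulder_right = "RightShoulder",
        elbow_left = "LeftElbow", elbow_right = "RightElbow"
      ),
      derived = list(
        spine_upper = list(rule = "midpoint",
                           sources = c("LeftCollar", "RightCollar"))
      )
    ),
    stop("no joint mapping for sensor ", sensor$name, call. = FALSE)
  )
  if (side == "right") {
    d <- m$direct
    swap <- function(v, i, j) { tmp <- v[[i]]; v[[i]] <- v[[j]]; v[[j]] <- tmp; v }
    d <- swap(d, "shoulder_left", "shoulder_right")
    d[["elbow_left"]] <- m$direct[["elbow_right"]]
    d[["elbow_right"]] <- m$direct[["elbow_left"]]
    m$direct <- d
  }
  # drop the trailing elbow from the canonical output set
  m$direct <- m$direct[setdiff(names(m$direct), "elbow_right")]
  structure(
    list(sensor = sensor, side = side,
         direct = m$direct, derived = m$derived),
    class = "joint_mapping"
  )
}

#' Export a joint mapping as a YAML document
#'
#' @param mapping A [joint_mapping()].
#' @param path Optional file path; when `NULL` the YAML text is returned.
#' @export
write_joint_mapping <- function(mapping, path = NULL) {
  stopifnot(inherits(mapping, "joint_mapping"))
  doc <- list(
    sensor = mapping$sensor$name,
    side = mapping$side,
    direct = as.list(mapping$direct),
    derived = lapply(mapping$derived, function(d) {
      list(rule = d$rule, sources = as.list(d$sources))
    })
  )
  txt <- yaml::as.yaml(doc)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}

#' Harmonize a sensor recording onto the canonical five-joint set
#'
#' Applies the sensor's [joint_mapping()] frame by frame (the operation is
#' stateless per frame). A derived joint is valid only when all of its source
#' joints are valid in that frame; midpoint derivation is exact up to
#' floating point.
#'
#' @param seq A `skeleton_sequence`.
#' @param side Leading side, `"left"` (default) or `"right"`.
#' @return A `canonical_transfer`: a data frame with one row per frame and
#'   columns `timestamp` plus `<joint>_x`, `<joint>_y`, `<joint>_z`,
#'   `<joint>_valid` for each of the five canonical joints. Sensor name,
#'   side and trial/subject labels are carried in attributes.
#' @examples
#' # Azure clavicles at (-100, 500, 2000) and (100, 500, 2000) mm give
#' # spine_upper = (0, 500, 2000)
#' @export
harmonize <- function(seq, side = c("left", "right")) {
  stopifnot(inherits(seq, "skeleton_sequence"))
  side <- match.arg(side)
  mapping <- joint_mapping(seq$sensor, side)
  n <- n_frames(seq)
  out <- data.frame(timestamp = seq$timestamps)
  get_joint <- function(src) {
    resolved <- match_joint(src, seq$joints)
    if (is.na(resolved)) {
      list(xyz = matrix(NA_real_, n, 3), valid = rep(FALSE, n))
    } else {
      list(xyz = joint_xyz(seq, resolved), valid = seq$valid[, resolved])
    }
  }
  for (canon in CANONICAL_JOINTS) {
    if (canon %in% names(mapping$direct)) {
      g <- get_joint(mapping$direct[[canon]])
      xyz <- g$xyz; valid <- g$valid
    } else {
      d <- mapping$derived[[canon]]
      stopifnot(identical(d$rule, "midpoint"))
      g1 <- get_joint(d$sources[1]); g2 <- get_joint(d$sources[2])
      xyz <- (g1$xyz + g2$xyz) / 2
      valid <- g1$valid & g2$valid
    }
    xyz[!valid, ] <- NA_real_
    out[[paste0(canon, "_x")]] <- xyz[, 1]
    out[[paste0(canon, "_y")]] <- xyz[, 2]
    out[[paste0(canon, "_z")]] <- xyz[, 3]
    out[[paste0(canon, "_valid")]] <- valid
  }
  # a coincident pelvis/upper-spine pair would degenerate the trunk vector
  both <- out$pelvis_valid & out$spine_upper_valid
  same <- both &
    out$pelvis_x == out$spine_upper_x &
    out$pelvis_y == out$spine_upper_y &
    out$pelvis_z == out$spine_upper_z
  if (any(same, na.rm = TRUE)) {
    out$spine_upper_valid[which(same)] <- FALSE
  }
  structure(out,
    class = c("canonical_transfer", "data.frame"),
    sensor = seq$sensor$name, side = side,
    trial_id = seq$trial_id, subject_id = seq$subject_id
  )
}

# canonical joint coordinates of one frame as a named list of 3-vectors
canonical_frame <- function(ct, i) {
  lapply(stats::setNames(nm = CANONICAL_JOINTS), function(j) {
    c(ct[[paste0(j, "_x")]][i], ct[[paste0(j, "_y")]][i],
      ct[[paste0(j, "_z")]][i])
  })
}

frame_valid <- function(ct, i, joints) {
  all(vapply(joints, function(j) isTRUE(ct[[paste0(j, "_valid")]][i]),
             logical(1)))
}
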