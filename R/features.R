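#' Unsigned angle between two 3-vectors
#'
#' `acos` of the clamped normalized dot product, in degrees, range
#' \[0, 180\].
#'
#' @param u,v Numeric 3-vectors with non-zero norm.
#' @return Angle in degrees.
#' @examples
#' angle_between(c(1, 0, 0), c(0, 1, 0)) # 90
#' @export
angle_between <- function(u, v) {
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) {
    stop("degenerate geometry: zero-length vector", call. = FALSE)
  }
  ct <- sum(u * v) / (nu * nv)
  acos(max(-1, min(1, ct))) * 180 / pi
}

#' Trunk basis of a canonical frame
#'
#' The trunk vector runs pelvis -> upper spine; the shoulder-across vector
#' runs left shoulder -> right shoulder; the chest normal is their cross
#' product, orthogonal to both.
#'
#' @param pelvis,spine_upper,shoulder_left,shoulder_right 3-vectors, mm.
#' @return List with `trunk`, `across`, `normal` (mm / mm^2-scaled
#'   directions).
#' @export
trunk_basis <- function(pelvis, spine_upper, shoulder_left, shoulder_right) {
  trunk <- spine_upper - pelvis
  across <- shoulder_right - shoulder_left
  if (sum(trunk^2) == 0) stop("degenerate trunk vector", call. = FALSE)
  if (sum(across^2) == 0) stop("degenerate shoulder-across vector",
                               call. = FALSE)
  normal <- cross3(trunk, across)
  if (sum(normal^2) == 0) {
    stop("degenerate chest normal: trunk and shoulder vectors are parallel",
         call. = FALSE)
  }
  list(trunk = trunk, across = across, normal = normal)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Trunk flexion angle of one frame
#'
#' Angle between the trunk vector (pelvis -> upper spine) and the vertical
#' y-axis: 0 deg upright, 90 deg horizontal.
#'
#' @param pelvis,spine_upper 3-vectors, mm.
#' @return Degrees in \[0, 180\].
#' @export
trunk_flexion <- function(pelvis, spine_upper) {
  angle_between(spine_upper - pelvis, c(0, 1, 0))
}

#' Shoulder elevation angle of one frame
#'
#' Angle between the trunk vector and the leading upper-arm vector
#' (shoulder -> elbow). An arm hanging along the trunk direction gives
#' 180 deg (the upper-arm vector points opposite the trunk vector).
#'
#' @param pelvis,spine_upper,shoulder,elbow 3-vectors, mm.
#' @return Degrees in \[0, 180\].
#' @export
elevation <- function(pelvis, spine_upper, shoulder, elbow) {
  angle_between(spine_upper - pelvis, elbow - shoulder)
}

#' Shoulder plane-of-elevation angle of one frame
#'
#' Horizontal-plane direction of the leading upper arm relative to the
#' chest-forward direction: both the chest normal and the upper-arm vector
#' are projected onto the transverse plane and the unsigned angle between
#' the projections is returned. 0 deg points straight ahead of the chest,
#' 90 deg straight out to the side.
#'
#' @param pelvis,spine_upper,shoulder_left,shoulder_right,elbow 3-vectors,
#'   mm. `elbow` belongs to the leading arm (same side as `shoulder_left`
#'   after any mirroring).
#' @param transverse `"body"` (default) projects onto the anatomical
#'   transverse plane, orthogonal to the trunk vector; `"lab"` projects onto
#'   the lab horizontal plane (normal = y-axis), for sensitivity analyses.
#' @return Degrees in \[0, 180\].
#' @export
plane_of_elevation <- function(pelvis, spine_upper, shoulder_left,
                               shoulder_right, elbow,
                               transverse = c("body", "lab")) {
  transverse <- match.arg(transverse)
  basis <- trunk_basis(pelvis, spine_upper, shoulder_left, shoulder_right)
  plane_normal <- if (transverse == "body") basis$trunk else c(0, 1, 0)
  arm <- elbow - shoulder_left
  pn <- plane_normal / sqrt(sum(plane_normal^2))
  proj <- function(v) v - sum(v * pn) * pn
  arm_p <- proj(arm)
  normal_p <- proj(basis$normal)
  if (sum(arm_p^2) < 1e-12 * sum(arm^2)) {
    stop("degenerate projection: upper arm is parallel to the trunk",
         call. = FALSE)
  }
  if (sum(normal_p^2) == 0) {
    stop("degenerate projection of the chest normal", call. = FALSE)
  }
  angle_between(arm_p, normal_p)
}

#' Pelvis displacement over the lift phase
#'
#' Final minus initial pelvis x-position across the detected lift window,
#' on the raw (unfiltered) series, converted from mm to cm. The
#' segmentation's direction flag makes the value positive for a completed
#' transfer regardless of the transfer direction.
#'
#' @param pelvis_x Raw pelvis x series, mm.
#' @param seg A [detect_phases()] result for the same series.
#' @return Displacement in cm.
#' @export
dswp <- function(pelvis_x, seg) {
  stopifnot(inherits(seg, "phase_segmentation"))
  i0 <- seg$lift_start_idx; i1 <- seg$lift_end_idx
  if (i0 < 1 || i1 > length(pelvis_x) || i0 >= i1) {
    stop("segmentation indices do not match the series", call. = FALSE)
  }
  x0 <- pelvis_x[i0]; x1 <- pelvis_x[i1]
  if (is.na(x0) || is.na(x1)) {
    # fall back to nearest observed samples inside the window
    obs <- which(!is.na(pelvis_x))
    x0 <- pelvis_x[obs[which.min(abs(obs - i0))]]
    x1 <- pelvis_x[obs[which.min(abs(obs - i1))]]
  }
  seg$direction * (x1 - x0) / 10
}

#' Extract the four lift-phase features from a harmonized transfer
#'
#' Computes, over the frames of the detected lift window (both endpoints
#' included), the arithmetic means of the per-frame trunk flexion (TF),
#' shoulder elevation (LE) and plane-of-elevation (LPOE) angles, plus the
#' pelvis displacement (DSWP). Angles are computed on the raw, unfiltered
#' joint coordinates; filtering is used only for phase detection. Frames
#' with a missing joint are excluded from that feature's mean only, and the
#' dropped fraction is reported; a trial with more than `max_dropped`
#' dropped for any feature is flagged low quality.
#'
#' @param ct A [harmonize()]d `canonical_transfer`.
#' @param seg A [detect_phases()] result for the same trial (if omitted it
#'   is computed from the pelvis x series at `rate`).
#' @param rate Sampling rate (Hz), needed only when `seg` is missing.
#' @param transverse Transverse-plane convention for LPOE, see
#'   [plane_of_elevation()].
#' @param max_dropped Dropped-frame fraction above which the trial is
#'   flagged low quality (default 0.25).
#' @return A `feature_set` list: `dswp` (cm), `lpoe`, `le`, `tf` (degrees,
#'   `NA` with a `reason` when no valid frame supports them),
#'   `n_lift_frames`, per-feature dropped fractions, `low_quality`, and the
#'   trial labels.
#' @export
extract_features <- function(ct, seg = NULL, rate = 30,
                             transverse = c("body", "lab"),
                             max_dropped = 0.25) {
  stopifnot(inherits(ct, "canonical_transfer"))
  transverse <- match.arg(transverse)
  pelvis_x <- ct$pelvis_x
  if (is.null(seg)) seg <- detect_phases(pelvis_x, rate)
  idx <- seq(seg$lift_start_idx, seg$lift_end_idx)
  n_lift <- length(idx)

  needed <- list(
    tf = c("pelvis", "spine_upper"),
    le = c("pelvis", "spine_upper", "shoulder_left", "elbow_left"),
    lpoe = CANONICAL_JOINTS
  )
  per_frame <- function(feature) {
    vals <- rep(NA_real_, n_lift)
    for (k in seq_along(idx)) {
      i <- idx[k]
      if (!frame_valid(ct, i, needed[[feature]])) next
      f <- canonical_frame(ct, i)
      vals[k] <- tryCatch(
        switch(feature,
          tf = trunk_flexion(f$pelvis, f$spine_upper),
          le = elevation(f$pelvis, f$spine_upper, f$shoulder_left,
                         f$elbow_left),
          lpoe = plane_of_elevation(f$pelvis, f$spine_upper, f$shoulder_left,
                                    f$shoulder_right, f$elbow_left,
                                    transverse)
        ),
        error = function(e) NA_real_
      )
    }
    vals
  }

  angles <- lapply(stats::setNames(nm = names(needed)), per_frame)
  dropped <- vapply(angles, function(v) mean(is.na(v)), numeric(1))
  means <- vapply(angles, function(v) {
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, numeric(1))
  reasons <- vapply(names(angles), function(f) {
    if (is.na(means[[f]])) "no valid lift-phase frame" else NA_character_
  }, character(1))

  structure(
    list(
      dswp = dswp(pelvis_x, seg),
      lpoe = means[["lpoe"]], le = means[["le"]], tf = means[["tf"]],
      n_lift_frames = n_lift,
      dropped_fraction = dropped,
      low_quality = any(dropped > max_dropped),
      missing_reason = reasons[!is.na(reasons)],
      trial_id = attr(ct, "trial_id"),
      subject_id = attr(ct, "subject_id"),
      sensor = attr(ct, "sensor")
    ),
    class = "feature_set"
  )
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf(
    "<feature_set> DSWP %.2f cm | LPOE %.1f deg | LE %.1f deg | TF %.1f deg (%d lift frames)\n",
    x$dswp, x$lpoe, x$le, x$tf, x$n_lift_frames))
  if (x$low_quality) cat("  flagged low quality (dropped frames)\n")
  invisible(x)
}

#' Convert feature sets to a data frame
#'
#' @param feature_sets A list of `feature_set` objects.
#' @return One row per trial with columns `sensor`, `subject_id`,
#'   `trial_id`, `dswp`, `lpoe`, `le`, `tf`, `n_lift_frames`,
#'   `low_quality`.
#' @export
features_df <- function(feature_sets) {
  do.call(rbind, lapply(feature_sets, function(f) {
    data.frame(
      sensor = f$sensor %||% NA_character_,
      subject_id = f$subject_id %||% NA_character_,
      trial_id = f$trial_id %||% NA_character_,
      dswp = f$dswp, lpoe = f$lpoe, le = f$le, tf = f$tf,
      n_lift_frames = f$n_lift_frames,
      low_quality = f$low_quality,
      stringsAsFactors = FALSE
    )
  }))
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0) b else a
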