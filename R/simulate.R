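#' Transfer motion profile
#'
#' Parameters of one simulated sitting-pivot transfer. Defaults are
#' calibrated so that noiseless extracted features sit at realistic
#' magnitudes for adult wheelchair users transferring to an adjacent bench
#' (pelvis travel just under half a metre; lift-phase mean plane of
#' elevation ~84 deg, elevation ~45 deg, trunk flexion ~31 deg).
#'
#' The pelvis x-trajectory is plateau / ramp / plateau: a linear rise of
#' `pelvis_travel` mm over `lift_duration` seconds with short smoothstep
#' (C1) corner blends, so the filtered trajectory shows clean plateaus and
#' a well-defined lift window. Angle profiles over the lift are raised
#' cosines, `m - amp * cos(2 pi s)` for lift progress `s` in \[0, 1\]
#' (value `m - amp` on the plateaus, continuous and C1 at the lift
#' boundaries), whose lift-phase mean is `m` in closed form.
#'
#' @param pelvis_travel Pelvis travel along the transfer axis, mm.
#' @param pre_duration,lift_duration,post_duration Phase durations, s.
#' @param tf_mean,le_mean,lpoe_mean Lift-phase mean trunk flexion,
#'   elevation and plane-of-elevation angles, degrees.
#' @param tf_amp,le_amp,lpoe_amp Within-lift excursion amplitudes, degrees.
#' @param side Leading side, `"left"` or `"right"`.
#' @param rate Frame rate, Hz.
#' @param trunk_length,shoulder_halfwidth,upper_arm_length,clavicle_halfwidth
#'   Rigid segment constants, mm.
#' @return A `transfer_profile` object.
#' @export
transfer_profile <- function(pelvis_travel = 477.5,
                             pre_duration = 2, lift_duration = 1,
                             post_duration = 2,
                             tf_mean = 31, le_mean = 45, lpoe_mean = 84,
                             tf_amp = 6, le_amp = 5, lpoe_amp = 5,
                             side = "left", rate = 30,
                             trunk_length = 500,
                             shoulder_halfwidth = 180,
                             upper_arm_length = 300,
                             clavicle_halfwidth = 40) {
  stopifnot(
    pre_duration > 0, lift_duration > 0, post_duration > 0,
    pelvis_travel > 100, rate > 0,
    tf_mean > tf_amp, tf_mean + tf_amp < 180,
    le_mean > le_amp, le_mean + le_amp < 180,
    lpoe_mean > lpoe_amp, lpoe_mean + lpoe_amp < 180
  )
  structure(as.list(environment()), class = "transfer_profile")
}

#' Sensor noise model for the simulator
#'
#' Emulates the dominant artefacts of depth-sensor body tracking: isotropic
#' Gaussian jitter on every joint coordinate, a constant tracking lag on
#' the pelvis joint (some sensors' pelvis estimate trails the true body
#' position), per-frame per-joint dropout (lost tracking, flagged missing),
#' and optional constant per-joint bias offsets.
#'
#' @param jitter_sd Jitter SD, mm per coordinate.
#' @param pelvis_lag Pelvis tracking lag, s.
#' @param dropout_prob Per-frame, per-joint probability of a missing joint.
#' @param bias Optional named list of 3-vectors (mm) added to specific
#'   canonical joints, e.g. `list(pelvis = c(5, 0, 0))`.
#' @param feature_noise_sd Optional named vector of per-feature measurement
#'   noise SDs (units of the feature) used by the feature-level session
#'   simulator, e.g. `c(dswp = 1, lpoe = 2, le = 2, tf = 2)`.
#' @return A `sensor_noise` object.
#' @export
sensor_noise <- function(jitter_sd = 0, pelvis_lag = 0, dropout_prob = 0,
                         bias = NULL, feature_noise_sd = NULL) {
  stopifnot(jitter_sd >= 0, dropout_prob >= 0, dropout_prob < 1)
  structure(
    list(jitter_sd = jitter_sd, pelvis_lag = pelvis_lag,
         dropout_prob = dropout_prob, bias = bias,
         feature_noise_sd = feature_noise_sd),
    class = "sensor_noise"
  )
}

# smoothstep-blended piecewise-linear ramp: 0 before t0, `travel` after t1,
# linear between, with C1 smoothstep corner blends of half-width `blend` s.
ramp_position <- function(t, t0, t1, travel, blend) {
  slope <- travel / (t1 - t0)
  sapply(t, function(ti) {
    if (ti <= t0 - blend) return(0)
    if (ti >= t1 + blend) return(travel)
    if (ti < t0 + blend) {
      # quadratic blend from slope 0 to `slope`
      u <- (ti - (t0 - blend)) / (2 * blend)
      return(slope * blend * u^2)
    }
    if (ti > t1 - blend) {
      u <- ((t1 + blend) - ti) / (2 * blend)
      return(travel - slope * blend * u^2)
    }
    slope * (ti - t0)
  })
}

# lift progress s in [0,1]; 0 outside the lift
lift_progress <- function(t, t0, t1) {
  pmin(1, pmax(0, (t - t0) / (t1 - t0)))
}

# deterministic substream seed (< 2^31) from a base seed and indices
substream_seed <- function(seed, ...) {
  idx <- c(...)
  h <- as.double(seed %% 2147483647)
  for (v in idx) {
    h <- (h * 48271 + as.double(v) * 3141593 + 7) %% 2147483629
  }
  as.integer(h %% 2147483647)
}

#' Simulate one transfer trial as seen by one sensor
#'
#' Generates the canonical five-joint kinematics of a sitting-pivot
#' transfer (minimal rigid-segment model: pelvis, trunk, shoulder girdle,
#' leading upper arm), renders it into the sensor's joint vocabulary, and
#' applies the sensor noise model. The true, noise-free lift-phase feature
#' means are returned in closed form together with the true lift window.
#'
#' The trunk flexes in the x-y plane (toward the transfer direction), so
#' trunk flexion equals the prescribed profile exactly; the arm direction
#' is constructed in the trunk/chest basis so that the elevation and
#' plane-of-elevation angles equal their prescribed profiles exactly.
#'
#' @param profile A [transfer_profile()].
#' @param sensor Sensor model or name rendering the trial.
#' @param noise A [sensor_noise()]; default noiseless.
#' @param seed Integer seed (deterministic: same seed, same output).
#' @param trial_id,subject_id Labels stamped on the sequence.
#' @return List with `sequence` (a `skeleton_sequence`), `truth` (list with
#'   `dswp` cm, `lpoe`, `le`, `tf` degrees, `lift_start_idx`,
#'   `lift_end_idx` 1-based frame indices of the nominal lift segment).
#' @export
simulate_trial <- function(profile, sensor = "KINECT_AZURE",
                           noise = sensor_noise(), seed = 1,
                           trial_id = "trial_1", subject_id = "subject_1") {
  stopifnot(inherits(profile, "transfer_profile"))
  if (!inherits(sensor, "sensor_model")) sensor <- sensor_model(sensor)
  p <- profile
  dt <- 1 / p$rate
  total <- p$pre_duration + p$lift_duration + p$post_duration
  t <- seq(0, total, by = dt)
  t0 <- p$pre_duration
  t1 <- p$pre_duration + p$lift_duration
  n_lift <- round(p$lift_duration * p$rate)
  blend <- max(1, round(0.05 * n_lift)) * dt

  # the lift window runs from blend start to blend end; angle profiles and
  # ground-truth indices use the same window the pelvis leaves/reaches its
  # plateaus in
  s <- lift_progress(t, t0 - blend, t1 + blend)
  px <- ramp_position(t, t0, t1, p$pelvis_travel, blend)
  py <- 600 + 50 * sin(pi * s)^2          # slight butt raise during lift
  pz <- rep(2000, length(t))

  deg <- pi / 180
  tf <- (p$tf_mean - p$tf_amp * cos(2 * pi * s)) * deg
  le <- (p$le_mean - p$le_amp * cos(2 * pi * s)) * deg
  lpoe <- (p$lpoe_mean - p$lpoe_amp * cos(2 * pi * s)) * deg

  n <- length(t)
  pelvis <- cbind(px, py, pz)
  # trunk tilts in the x-y plane toward +x
  t_hat <- cbind(sin(tf), cos(tf), 0)
  spine_upper <- pelvis + p$trunk_length * t_hat
  a_hat <- cbind(0 * tf, 0 * tf, 1)       # left -> right, perpendicular to trunk
  n_hat <- cbind(cos(tf), -sin(tf), 0 * tf)  # cross(t_hat, a_hat), unit
  b_hat <- -a_hat                          # cross(t_hat, n_hat)
  shoulder_left <- spine_upper - p$shoulder_halfwidth * a_hat
  shoulder_right <- spine_upper + p$shoulder_halfwidth * a_hat
  arm_dir <- cos(le) * t_hat +
    sin(le) * (cos(lpoe) * n_hat + sin(lpoe) * b_hat)
  elbow_left <- shoulder_left + p$upper_arm_length * arm_dir
  clav_left <- spine_upper - p$clavicle_halfwidth * a_hat
  clav_right <- spine_upper + p$clavicle_halfwidth * a_hat

  # pelvis tracking lag: the sensor reports the pelvis where it was `lag` ago
  if (noise$pelvis_lag != 0) {
    tl <- t - noise$pelvis_lag
    pelvis <- cbind(
      ramp_position(tl, t0, t1, p$pelvis_travel, blend),
      600 + 50 * sin(pi * lift_progress(tl, t0 - blend, t1 + blend))^2,
      pz
    )
  }

  canon <- list(
    pelvis = pelvis, spine_upper = spine_upper,
    shoulder_left = shoulder_left, shoulder_right = shoulder_right,
    elbow_left = elbow_left,
    clavicle_left = clav_left, clavicle_right = clav_right
  )
  if (!is.null(noise$bias)) {
    for (jn in names(noise$bias)) {
      if (jn %in% names(canon)) {
        canon[[jn]] <- sweep(canon[[jn]], 2, noise$bias[[jn]], "+")
      }
    }
  }

  vocab_map <- switch(sensor$name,
    KINECT_V2 = c(pelvis = "SpineBase", spine_upper = "SpineShoulder",
                  shoulder_left = "ShoulderLeft",
                  shoulder_right = "ShoulderRight",
                  elbow_left = "ElbowLeft"),
    KINECT_AZURE = c(pelvis = "Pelvis",
                     clavicle_left = "ClavicleLeft",
                     clavicle_right = "ClavicleRight",
                     shoulder_left = "ShoulderLeft",
                     shoulder_right = "ShoulderRight",
                     elbow_left = "ElbowLeft"),
    REALSENSE_NUITRACK = c(pelvis = "Waist",
                           clavicle_left = "LeftCollar",
                           clavicle_right = "RightCollar",
                           shoulder_left = "LeftShoulder",
                           shoulder_right = "RightShoulder",
                           elbow_left = "LeftElbow")
  )

  withr_seed <- function(s, expr) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(s)
    expr
  }

  joints <- unname(vocab_map)
  j <- length(joints)
  xyz <- array(NA_real_, c(n, j, 3))
  for (k in seq_len(j)) xyz[, k, ] <- canon[[names(vocab_map)[k]]]
  valid <- matrix(TRUE, n, j)
  withr_seed(substream_seed(seed, 1), {
    if (noise$jitter_sd > 0) {
      xyz <- xyz + array(stats::rnorm(n * j * 3, 0, noise$jitter_sd),
                         c(n, j, 3))
    }
    if (noise$dropout_prob > 0) {
      valid <- matrix(stats::runif(n * j) >= noise$dropout_prob, n, j)
    }
  })

  sequence <- skeleton_sequence(sensor, t, joints, xyz, valid,
                                trial_id = trial_id,
                                subject_id = subject_id)
  truth <- list(
    dswp = p$pelvis_travel / 10,
    lpoe = p$lpoe_mean, le = p$le_mean, tf = p$tf_mean,
    lift_start_idx = which.min(abs(t - (t0 - blend))),
    lift_end_idx = which.min(abs(t - (t1 + blend))),
    rate = p$rate
  )
  list(sequence = sequence, truth = truth)
}

#' Multi-subject, multi-sensor session design
#'
#' Describes a simulated data-collection session: a cohort of subjects each
#' performing repeated transfers, recorded simultaneously by one or more
#' sensors. Subject-level true feature means are drawn around the base
#' profile with the stated between-subject SDs; each trial deviates from
#' its subject mean with the within-subject SDs; each sensor then adds its
#' own measurement noise. This is the variance structure the reliability
#' statistics assume (targets x raters with separable variance components).
#'
#' @param n_subjects Number of subjects (>= 2 for reliability designs).
#' @param trials_per_subject Repeated transfers per subject.
#' @param between_subject_sd,within_subject_sd Named numeric vectors with
#'   entries `dswp` (cm), `lpoe`, `le`, `tf` (degrees).
#' @param sensors Named list of [sensor_noise()] models; names are sensor
#'   model names (e.g. `KINECT_AZURE`).
#' @param base_profile The cohort-mean [transfer_profile()].
#' @param plan Optional data frame (`subject`, `trial`, `transfer_type`)
#'   listing transfer types per trial; defaults to all `"good"`.
#' @param score_flip_prob Per-item probability that a simulated predicted
#'   score disagrees with the ground truth (emulates classifier error).
#' @return A `session_design` object.
#' @export
session_design <- function(n_subjects = 7, trials_per_subject = 10,
                           between_subject_sd =
                             c(dswp = 5.2, lpoe = 5.3, le = 5.0, tf = 7.0),
                           within_subject_sd =
                             c(dswp = 1.5, lpoe = 1.6, le = 1.5, tf = 2.1),
                           sensors = list(
                             KINECT_AZURE = sensor_noise(jitter_sd = 2),
                             KINECT_V2 = sensor_noise(jitter_sd = 3)
                           ),
                           base_profile = transfer_profile(),
                           plan = NULL,
                           score_flip_prob = 0.08) {
  stopifnot(n_subjects >= 2, trials_per_subject >= 1)
  feats <- c("dswp", "lpoe", "le", "tf")
  stopifnot(all(feats %in% names(between_subject_sd)),
            all(feats %in% names(within_subject_sd)))
  if (is.null(plan)) {
    plan <- expand.grid(trial = seq_len(trials_per_subject),
                        subject = seq_len(n_subjects))[, c("subject", "trial")]
    plan$transfer_type <- "good"
  }
  structure(
    list(n_subjects = n_subjects, trials_per_subject = trials_per_subject,
         between_subject_sd = between_subject_sd,
         within_subject_sd = within_subject_sd,
         sensors = sensors, base_profile = base_profile, plan = plan,
         score_flip_prob = score_flip_prob),
    class = "session_design"
  )
}

# improper techniques alter the motion: low trunk lean for "trunk",
# arm further out for "arm"; "feet" and "fist" do not move the five
# modeled joints.
apply_transfer_type <- function(means, transfer_type) {
  switch(transfer_type,
    trunk = { means[["tf"]] <- means[["tf"]] * 0.4; means },
    arm = { means[["lpoe"]] <- min(170, means[["lpoe"]] + 25); means },
    means
  )
}

#' Simulate a full session
#'
#' Draws subject means and trial deviations per [session_design()], then
#' either renders every trial through every sensor's noise model into
#' skeletal recordings (`render = "recordings"`) or returns the per-trial
#' measured features directly (`render = "features"`: measured value =
#' subject mean + trial deviation + sensor feature noise), which is orders
#' of magnitude faster and exposes the same variance structure to the
#' reliability estimators. Ground-truth and simulated predicted score
#' tables are produced per [ground_truth_table()].
#'
#' RNG substreams are split per (subject, trial, sensor), so adding a
#' sensor leaves existing trials' draws unchanged.
#'
#' @param design A [session_design()].
#' @param seed Integer master seed.
#' @param render `"recordings"` or `"features"`.
#' @return List with `recordings` (named list
#'   `<sensor>/<subject>/<trial> -> skeleton_sequence`, only when
#'   rendering), `features_true` (per-trial true feature data frame),
#'   `features_measured` (per sensor; only for `render = "features"`),
#'   `score_truth` (a [score_table()]), `score_pred` (named list of
#'   predicted [score_table()]s per sensor), and `plan`.
#' @export
simulate_session <- function(design, seed = 1,
                             render = c("recordings", "features")) {
  stopifnot(inherits(design, "session_design"))
  render <- match.arg(render)
  feats <- c("dswp", "lpoe", "le", "tf")
  base <- design$base_profile
  base_means <- c(dswp = base$pelvis_travel / 10, lpoe = base$lpoe_mean,
                  le = base$le_mean, tf = base$tf_mean)
  plan <- design$plan
  plan$trial_id <- sprintf("s%02d_t%02d", plan$subject, plan$trial)

  with_seed <- function(s, expr) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(s)
    expr
  }

  subjects <- sort(unique(plan$subject))
  subj_means <- lapply(stats::setNames(nm = subjects), function(s) {
    with_seed(substream_seed(seed, 10, s), {
      base_means + stats::rnorm(4, 0, design$between_subject_sd[feats])
    })
  })

  truth_rows <- list()
  recordings <- list()
  measured <- lapply(design$sensors, function(x) list())
  for (i in seq_len(nrow(plan))) {
    s <- plan$subject[i]; tr <- plan$trial[i]
    tt <- plan$transfer_type[i]
    means <- with_seed(substream_seed(seed, 20, s, tr), {
      m <- subj_means[[as.character(s)]] +
        stats::rnorm(4, 0, design$within_subject_sd[feats])
      names(m) <- feats
      m
    })
    means <- apply_transfer_type(means, tt)
    # keep the motion physically sane
    means[["dswp"]] <- max(means[["dswp"]], 15)
    means[["tf"]] <- min(max(means[["tf"]], base$tf_amp + 1), 170)
    means[["le"]] <- min(max(means[["le"]], base$le_amp + 1), 170)
    means[["lpoe"]] <- min(max(means[["lpoe"]], base$lpoe_amp + 1), 170)
    truth_rows[[i]] <- data.frame(
      subject_id = as.character(s), trial_id = plan$trial_id[i],
      transfer_type = tt,
      dswp = means[["dswp"]], lpoe = means[["lpoe"]],
      le = means[["le"]], tf = means[["tf"]]
    )
    for (sn in names(design$sensors)) {
      nz <- design$sensors[[sn]]
      si <- match(sn, names(design$sensors))
      if (render == "recordings") {
        prof <- transfer_profile(
          pelvis_travel = means[["dswp"]] * 10,
          pre_duration = base$pre_duration,
          lift_duration = base$lift_duration,
          post_duration = base$post_duration,
          tf_mean = means[["tf"]], le_mean = means[["le"]],
          lpoe_mean = means[["lpoe"]],
          tf_amp = base$tf_amp, le_amp = base$le_amp,
          lpoe_amp = base$lpoe_amp,
          rate = base$rate,
          trunk_length = base$trunk_length,
          shoulder_halfwidth = base$shoulder_halfwidth,
          upper_arm_length = base$upper_arm_length
        )
        tri <- simulate_trial(
          prof, sensor = sn, noise = nz,
          seed = substream_seed(seed, 30, s, tr, si),
          trial_id = plan$trial_id[i], subject_id = as.character(s)
        )
        recordings[[paste(sn, plan$trial_id[i], sep = "/")]] <- tri$sequence
      } else {
        fnsd <- nz$feature_noise_sd
        if (is.null(fnsd)) fnsd <- c(dswp = 0, lpoe = 0, le = 0, tf = 0)
        obs <- with_seed(substream_seed(seed, 30, s, tr, si), {
          means + stats::rnorm(4, 0, fnsd[feats])
        })
        measured[[sn]][[length(measured[[sn]]) + 1]] <- data.frame(
          sensor = sn, subject_id = as.character(s),
          trial_id = plan$trial_id[i],
          dswp = obs[["dswp"]], lpoe = obs[["lpoe"]],
          le = obs[["le"]], tf = obs[["tf"]]
        )
      }
    }
  }

  score_truth <- ground_truth_table(plan)
  score_pred <- lapply(stats::setNames(nm = names(design$sensors)),
    function(sn) {
      si <- match(sn, names(design$sensors))
      flips <- with_seed(substream_seed(seed, 40, si), {
        matrix(stats::runif(nrow(plan) * length(score_truth$items)) <
                 design$score_flip_prob,
               nrow(plan), length(score_truth$items))
      })
      scores <- score_truth$scores
      scores[flips] <- 1L - scores[flips]
      score_table(scores, score_truth$items,
                  trial_id = plan$trial_id,
                  subject = as.character(plan$subject),
                  transfer_type = plan$transfer_type)
    })

  out <- list(
    features_true = do.call(rbind, truth_rows),
    score_truth = score_truth,
    score_pred = score_pred,
    plan = plan
  )
  if (render == "recordings") {
    out$recordings <- recordings
  } else {
    out$features_measured <- do.call(
      rbind, lapply(measured, function(l) do.call(rbind, l)))
    rownames(out$features_measured) <- NULL
  }
  out
}

#' Write a simulated session's recordings to a directory
#'
#' One CSV per (sensor, trial) via [write_recording()], named
#' `<sensor>__<trial_id>.csv`, plus `features_true.csv`,
#' `score_truth.csv`, and `score_pred_<sensor>.csv`.
#'
#' @param session A [simulate_session()] result with recordings.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  stopifnot(!is.null(session$recordings))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (key in names(session$recordings)) {
    fname <- paste0(gsub("/", "__", key), ".csv")
    write_recording(session$recordings[[key]], file.path(dir, fname))
  }
  utils::write.csv(session$features_true,
                   file.path(dir, "features_true.csv"), row.names = FALSE)
  write_score_table(session$score_truth, file.path(dir, "score_truth.csv"))
  for (sn in names(session$score_pred)) {
    write_score_table(session$score_pred[[sn]],
                      file.path(dir, paste0("score_pred_", sn, ".csv")))
  }
  invisible(dir)
}
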