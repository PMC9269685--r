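# Fixture builders shared across the suite. Everything is generated in code;
# no data files.

# random but well-formed skeleton sequence for round-trip properties
random_sequence <- function(seed, sensor = "KINECT_AZURE", n = 10,
                            joints = c("Pelvis", "ShoulderLeft", "ElbowLeft"),
                            missing_prob = 0.1) {
  set.seed(seed)
  j <- length(joints)
  xyz <- array(rnorm(n * j * 3, 0, 500), c(n, j, 3))
  valid <- matrix(runif(n * j) > missing_prob, n, j)
  skeleton_sequence(
    sensor, cumsum(runif(n, 0.02, 0.05)), joints, xyz, valid,
    trial_id = paste0("t", seed), subject_id = "s1"
  )
}

# canonical transfer with a fixed pose held over n frames
constant_pose_transfer <- function(n = 20,
                                   pelvis = c(0, 0, 2000),
                                   spine_upper = c(0, 500, 2000),
                                   shoulder_left = c(-180, 500, 2000),
                                   shoulder_right = c(180, 500, 2000),
                                   elbow_left = c(-180, 200, 2000),
                                   timestamps = (seq_len(n) - 1) / 30) {
  df <- data.frame(timestamp = timestamps)
  pts <- list(pelvis = pelvis, spine_upper = spine_upper,
              shoulder_left = shoulder_left,
              shoulder_right = shoulder_right, elbow_left = elbow_left)
  for (jn in names(pts)) {
    df[[paste0(jn, "_x")]] <- rep(pts[[jn]][1], n)
    df[[paste0(jn, "_y")]] <- rep(pts[[jn]][2], n)
    df[[paste0(jn, "_z")]] <- rep(pts[[jn]][3], n)
    df[[paste0(jn, "_valid")]] <- rep(TRUE, n)
  }
  structure(df, class = c("canonical_transfer", "data.frame"),
            sensor = "SYNTH", side = "left",
            trial_id = "t1", subject_id = "s1")
}

# apply a rigid transform (rotation matrix R, translation tr, scale c) to
# every joint of a canonical transfer
transform_transfer <- function(ct, R = diag(3), tr = c(0, 0, 0), scale = 1) {
  out <- ct
  for (jn in transferkin::CANONICAL_JOINTS) {
    cols <- paste0(jn, c("_x", "_y", "_z"))
    m <- as.matrix(ct[cols])
    m2 <- scale * (m %*% t(R))
    m2 <- sweep(m2, 2, tr, "+")
    out[cols] <- m2
  }
  out
}

rot_y <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), 0, sin(a), 0, 1, 0, -sin(a), 0, cos(a)), 3, 3,
         byrow = TRUE)
}

rot_z <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, 3,
         byrow = TRUE)
}

# plateau / linear ramp / plateau pelvis series (1-based truth: last plateau
# frame = n_pre, first landing frame = n_pre + n_ramp + 1)
ramp_series <- function(n_pre = 60, n_ramp = 30, n_post = 60, travel = 500) {
  c(rep(0, n_pre),
    seq(0, travel, length.out = n_ramp + 2)[2:(n_ramp + 1)],
    rep(travel, n_post))
}

# independent two-way ANOVA mean squares via stats::aov (oracle for icc())
aov_mean_squares <- function(m) {
  n <- nrow(m); k <- ncol(m)
  d <- data.frame(
    y = as.vector(m),
    target = factor(rep(seq_len(n), times = k)),
    rater = factor(rep(seq_len(k), each = n))
  )
  tab <- summary(stats::aov(y ~ target + rater, data = d))[[1]]
  list(msr = tab["target", "Mean Sq"],
       msc = tab["rater", "Mean Sq"],
       mse = tab["Residuals", "Mean Sq"])
}

# brute-force ICC from aov mean squares
oracle_icc <- function(m, model) {
  ms <- aov_mean_squares(m)
  n <- nrow(m); k <- ncol(m)
  if (model == "ICC_3_1") {
    (ms$msr - ms$mse) / (ms$msr + (k - 1) * ms$mse)
  } else {
    (ms$msr - ms$mse) /
      (ms$msr + (k - 1) * ms$mse + (k / n) * (ms$msc - ms$mse))
  }
}
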