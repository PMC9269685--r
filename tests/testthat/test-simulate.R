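test_that("the simulator is deterministic in its seed", {
  p <- transfer_profile()
  nz <- sensor_noise(jitter_sd = 3, dropout_prob = 0.02)
  a <- simulate_trial(p, "KINECT_V2", nz, seed = 42)
  b <- simulate_trial(p, "KINECT_V2", nz, seed = 42)
  expect_identical(a$sequence$xyz, b$sequence$xyz)
  expect_identical(a$sequence$valid, b$sequence$valid)
  c2 <- simulate_trial(p, "KINECT_V2", nz, seed = 43)
  expect_false(identical(a$sequence$xyz, c2$sequence$xyz))
})

test_that("noiseless trials recover the analytic features end to end", {
  set.seed(18)
  for (i in 1:10) {
    p <- transfer_profile(
      pelvis_travel = runif(1, 300, 650),
      lift_duration = runif(1, 0.8, 1.6),
      tf_mean = runif(1, 20, 45), le_mean = runif(1, 35, 60),
      lpoe_mean = runif(1, 70, 100)
    )
    for (sensor in c("KINECT_AZURE", "KINECT_V2", "REALSENSE_NUITRACK")) {
      tr <- simulate_trial(p, sensor, seed = i)
      ct <- harmonize(tr$sequence)
      seg <- detect_phases(ct$pelvis_x, p$rate)
      fs <- extract_features(ct, seg)
      expect_lt(abs(fs$dswp - tr$truth$dswp), 0.5)
      expect_lt(abs(fs$tf - tr$truth$tf), 1)
      expect_lt(abs(fs$le - tr$truth$le), 1)
      expect_lt(abs(fs$lpoe - tr$truth$lpoe), 1)
    }
  }
})

test_that("a pelvis tracking lag shifts the detected lift window", {
  p <- transfer_profile()
  tr <- simulate_trial(p, "KINECT_V2", sensor_noise(pelvis_lag = 0.1),
                       seed = 2)
  ct <- harmonize(tr$sequence)
  seg <- detect_phases(ct$pelvis_x, p$rate)
  # 0.1 s at 30 Hz = 3 frames late
  expect_equal(seg$lift_start_idx - tr$truth$lift_start_idx, 3,
               tolerance = 1)
  expect_equal(seg$lift_end_idx - tr$truth$lift_end_idx, 3, tolerance = 1)
})

test_that("severe dropout makes the pipeline fail loudly", {
  p <- transfer_profile()
  tr <- simulate_trial(p, "KINECT_V2", sensor_noise(dropout_prob = 0.9),
                       seed = 3)
  ct <- harmonize(tr$sequence)
  expect_error(detect_phases(ct$pelvis_x, p$rate), "missing run")
})

test_that("a constant sensor bias leaves angles intact but offsets positions", {
  p <- transfer_profile()
  plain <- simulate_trial(p, "KINECT_V2", seed = 4)
  biased <- simulate_trial(p, "KINECT_V2",
                           sensor_noise(bias = list(pelvis = c(25, 0, 0))),
                           seed = 4)
  px_a <- joint_xyz(plain$sequence, "SpineBase")[, "x"]
  px_b <- joint_xyz(biased$sequence, "SpineBase")[, "x"]
  expect_equal(px_b - px_a, rep(25, length(px_a)))
})

test_that("session plans produce the expected trial counts", {
  des <- session_design(
    n_subjects = 3, trials_per_subject = 50,
    sensors = list(KINECT_AZURE = sensor_noise(), KINECT_V2 = sensor_noise()),
    plan = data.frame(
      subject = rep(1:3, each = 50), trial = rep(1:50, 3),
      transfer_type = rep(rep(c("good", "feet", "trunk", "arm", "fist"),
                              each = 10), 3))
  )
  ses <- simulate_session(des, seed = 1, render = "features")
  expect_equal(nrow(ses$plan), 150)
  expect_equal(nrow(ses$features_measured), 300) # 150 trials x 2 sensors
  expect_equal(nrow(ses$score_truth$scores), 150)
  expect_named(ses$score_pred, c("KINECT_AZURE", "KINECT_V2"))
})

test_that("rendered sessions write one recording per sensor and trial", {
  des <- session_design(n_subjects = 2, trials_per_subject = 2,
                        sensors = list(KINECT_AZURE = sensor_noise(),
                                       KINECT_V2 = sensor_noise()))
  ses <- simulate_session(des, seed = 1, render = "recordings")
  expect_length(ses$recordings, 8)
  dir <- withr::local_tempdir()
  write_session(ses, dir)
  files <- list.files(dir, pattern = "__.*\\.csv$")
  expect_length(files, 8)
  back <- read_recording(
    file.path(dir, files[1]),
    strsplit(files[1], "__")[[1]][1])
  expect_s3_class(back, "skeleton_sequence")
})

test_that("two identical sensors agree perfectly across a session", {
  des <- session_design(
    n_subjects = 4, trials_per_subject = 3,
    sensors = list(A1 = sensor_noise(), A2 = sensor_noise())
  )
  # identical (noise-free) sensors measure the same trial values
  ses <- simulate_session(des, seed = 2, render = "features")
  f <- ses$features_measured
  a <- f[f$sensor == "A1", ]; b <- f[f$sensor == "A2", ]
  expect_equal(a$tf, b$tf)
  m <- cbind(a$tf, b$tf)
  expect_equal(icc(m, "ICC_2_1")$icc, 1)
})

test_that("feature-level sessions reproduce the designed variance ratio", {
  des <- session_design(
    n_subjects = 200, trials_per_subject = 2,
    between_subject_sd = c(dswp = 3, lpoe = 3, le = 3, tf = 3),
    within_subject_sd = c(dswp = 1, lpoe = 1, le = 1, tf = 1),
    sensors = list(KINECT_AZURE = sensor_noise())
  )
  ses <- simulate_session(des, seed = 6, render = "features")
  f <- ses$features_measured
  m <- do.call(rbind, lapply(split(f$tf, f$subject_id), function(v) v[1:2]))
  r <- icc(m, "ICC_3_1")
  expect_lt(abs(r$icc - 0.9), 0.05)
})

test_that("more jitter never improves reliability (monotone degradation)", {
  p <- transfer_profile()
  iccs <- vapply(c(0, 5, 15, 40), function(j) {
    vals <- t(vapply(1:12, function(s) {
      tr <- simulate_trial(p, "KINECT_AZURE", sensor_noise(jitter_sd = j),
                           seed = s)
      ct <- harmonize(tr$sequence)
      seg <- detect_phases(ct$pelvis_x, p$rate)
      fs <- extract_features(ct, seg)
      c(fs$tf, fs$le)
    }, numeric(2)))
    stats::var(vals[, 1]) # measurement variance of TF across seeds
  }, numeric(1))
  # variance about the fixed truth grows with jitter; allow ties at 0
  expect_true(all(diff(iccs) >= -1e-9))
})

test_that("improper transfer types alter the targeted kinematics", {
  means <- c(dswp = 47, lpoe = 84, le = 45, tf = 31)
  trunk <- apply_transfer_type(means, "trunk")
  expect_lt(trunk[["tf"]], means[["tf"]])
  arm <- apply_transfer_type(means, "arm")
  expect_gt(arm[["lpoe"]], means[["lpoe"]])
  expect_identical(apply_transfer_type(means, "feet"), means)
})
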