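test_that("angle_between matches the textbook cases", {
  expect_equal(angle_between(c(1, 0, 0), c(0, 1, 0)), 90)
  expect_equal(angle_between(c(1, 0, 0), c(1, 0, 0)), 0)
  expect_equal(angle_between(c(1, 1, 0), c(1, 0, 0)), 45)
  expect_equal(angle_between(c(1, 0, 0), c(-2, 0, 0)), 180)
  expect_error(angle_between(c(0, 0, 0), c(1, 0, 0)), "degenerate")
})

test_that("trunk flexion is the angle from vertical", {
  expect_equal(trunk_flexion(c(0, 0, 0), c(0, 500, 0)), 0)
  expect_equal(trunk_flexion(c(0, 0, 0), c(0, 1, 1) / sqrt(2)), 45)
  expect_equal(trunk_flexion(c(0, 0, 0), c(500, 0, 0)), 90)
})

test_that("elevation covers the parallel and perpendicular arm cases", {
  pelvis <- c(0, 0, 0); spine <- c(0, 500, 0); shoulder <- c(-180, 500, 0)
  # arm along -trunk (hanging)
  expect_equal(elevation(pelvis, spine, shoulder, shoulder + c(0, -300, 0)),
               180)
  # arm along +trunk
  expect_equal(elevation(pelvis, spine, shoulder, shoulder + c(0, 300, 0)), 0)
  # arm perpendicular to trunk
  expect_equal(elevation(pelvis, spine, shoulder, shoulder + c(0, 0, 300)),
               90)
})

test_that("plane of elevation separates forward from abducted arms", {
  pelvis <- c(0, 0, 0); spine <- c(0, 500, 0)
  sl <- c(-180, 500, 0); sr <- c(180, 500, 0)
  # chest normal = cross(trunk, across) = cross(+y, +x) = -z: forward is -z
  expect_equal(
    plane_of_elevation(pelvis, spine, sl, sr, sl + c(0, 0, -300)), 0)
  # arm straight out to the left (-x), orthogonal to the chest normal
  expect_equal(
    plane_of_elevation(pelvis, spine, sl, sr, sl + c(-300, 0, 0)), 90)
  # arm parallel to the trunk projects to nothing
  expect_error(
    plane_of_elevation(pelvis, spine, sl, sr, sl + c(0, 300, 0)),
    "degenerate projection")
})

test_that("angles match a brute-force Gram-Schmidt oracle on random frames", {
  brute_lpoe <- function(p, su, sl, sr, el) {
    trunk <- su - p
    normal <- pracma::cross(trunk, sr - sl)
    tn <- trunk / sqrt(sum(trunk^2))
    strip <- function(v) v - sum(v * tn) * tn
    a <- strip(el - sl); b <- strip(normal)
    acos(min(1, max(-1, sum(a * b) / sqrt(sum(a^2) * sum(b^2))))) * 180 / pi
  }
  brute_le <- function(p, su, sl, el) {
    u <- su - p; v <- el - sl
    acos(min(1, max(-1, sum(u * v) / sqrt(sum(u^2) * sum(v^2))))) * 180 / pi
  }
  set.seed(21)
  for (i in 1:25) {
    p <- rnorm(3, 0, 300); su <- p + rnorm(3, c(0, 500, 0), 100)
    sl <- su + rnorm(3, c(-180, 0, 0), 50)
    sr <- su + rnorm(3, c(180, 0, 0), 50)
    el <- sl + rnorm(3, c(0, -100, -200), 150)
    expect_equal(plane_of_elevation(p, su, sl, sr, el),
                 brute_lpoe(p, su, sl, sr, el), tolerance = 1e-9)
    expect_equal(elevation(p, su, sl, el), brute_le(p, su, sl, el),
                 tolerance = 1e-9)
  }
})

test_that("the trunk basis is mutually orthogonal", {
  b <- trunk_basis(c(0, 0, 0), c(10, 500, 5), c(-180, 480, 0),
                   c(175, 510, 10))
  expect_lt(abs(sum(b$normal * b$trunk)), 1e-8)
  expect_lt(abs(sum(b$normal * b$across)), 1e-8)
})

test_that("dswp is the scaled displacement over the lift window", {
  x <- ramp_series(travel = 500)
  seg <- detect_phases(x, 30)
  expect_equal(dswp(x, seg), 50, tolerance = 0.5)
  # plain arithmetic on hand-built indices
  seg2 <- seg; seg2$lift_start_idx <- 10; seg2$lift_end_idx <- 100
  x2 <- seq_len(120) * 10
  expect_equal(dswp(x2, seg2), (1000 - 100) / 10)
  # backward transfer still reports positive displacement
  segb <- detect_phases(-x, 30)
  expect_gt(dswp(-x, segb), 0)
})

test_that("a constant pose averages to its single-frame value", {
  ct <- constant_pose_transfer(n = 150)
  # translate the whole body along the transfer axis: every frame is the
  # same pose, so each angle mean equals its single-frame value
  shift <- ramp_series()
  for (jn in CANONICAL_JOINTS) {
    col <- paste0(jn, "_x")
    ct[[col]] <- ct[[col]] + shift
  }
  fs <- extract_features(ct, detect_phases(ct$pelvis_x, 30))
  one <- canonical_frame(ct, 75)
  expect_equal(fs$tf, trunk_flexion(one$pelvis, one$spine_upper))
  expect_equal(fs$le, elevation(one$pelvis, one$spine_upper,
                                one$shoulder_left, one$elbow_left))
})

test_that("a linear ramp of trunk flexion averages to its midpoint", {
  n <- 150
  ct <- constant_pose_transfer(n = n)
  ct$pelvis_x <- ramp_series()
  seg <- detect_phases(ct$pelvis_x, 30)
  idx <- seq(seg$lift_start_idx, seg$lift_end_idx)
  # tilt the trunk 10 -> 50 degrees linearly across the lift window
  ang <- rep(10, n)
  ang[idx] <- seq(10, 50, length.out = length(idx))
  ang <- ang * pi / 180
  ct$spine_upper_x <- ct$pelvis_x + 500 * sin(ang)
  ct$spine_upper_y <- 500 * cos(ang)
  fs <- extract_features(ct, seg)
  expect_equal(fs$tf, 30, tolerance = 0.2)
})

test_that("frames with missing joints are excluded per feature and reported", {
  n <- 150
  ct <- constant_pose_transfer(n = n)
  ct$pelvis_x <- ramp_series()
  seg <- detect_phases(ct$pelvis_x, 30)
  idx <- seq(seg$lift_start_idx, seg$lift_end_idx)
  # elbow missing in half the lift frames: LE/LPOE lose frames, TF does not
  drop <- idx[seq_along(idx) %% 2 == 0]
  ct$elbow_left_valid[drop] <- FALSE
  fs <- extract_features(ct, seg)
  expect_equal(fs$dropped_fraction[["tf"]], 0)
  expect_gt(fs$dropped_fraction[["le"]], 0.4)
  expect_true(fs$low_quality)
  expect_false(is.na(fs$le)) # still computable from the remaining frames
})

test_that("a feature with zero valid frames is missing with a reason", {
  ct <- constant_pose_transfer(n = 150)
  ct$pelvis_x <- ramp_series()
  seg <- detect_phases(ct$pelvis_x, 30)
  ct$elbow_left_valid[] <- FALSE
  fs <- extract_features(ct, seg)
  expect_true(is.na(fs$le))
  expect_true(is.na(fs$lpoe))
  expect_false(is.na(fs$tf))
  expect_true("le" %in% names(fs$missing_reason))
})

test_that("angle features are invariant to translation and scaling", {
  ct <- constant_pose_transfer(n = 150)
  ct$pelvis_x <- ramp_series()
  ct$spine_upper_x <- ct$pelvis_x + 150 # leaned trunk
  seg <- detect_phases(ct$pelvis_x, 30)
  fs <- extract_features(ct, seg)
  ct_t <- transform_transfer(ct, tr = c(1000, -500, 250), scale = 2)
  fs_t <- extract_features(ct_t, detect_phases(ct_t$pelvis_x, 30))
  expect_equal(fs_t$tf, fs$tf, tolerance = 1e-8)
  expect_equal(fs_t$le, fs$le, tolerance = 1e-8)
  expect_equal(fs_t$lpoe, fs$lpoe, tolerance = 1e-8)
  # displacement scales with the coordinates
  expect_equal(fs_t$dswp, 2 * fs$dswp, tolerance = 1e-6)
})

test_that("TF follows the lab vertical while LE and LPOE are body-referenced", {
  ct <- constant_pose_transfer(n = 150)
  ct$pelvis_x <- ramp_series()
  ct$spine_upper_x <- ct$pelvis_x + 150
  seg <- detect_phases(ct$pelvis_x, 30)
  fs <- extract_features(ct, seg)
  # rotation about the vertical axis: all features unchanged
  ct_y <- transform_transfer(ct, R = rot_y(35))
  # the rotated pelvis x-trajectory still supports segmentation
  fs_y <- extract_features(ct_y, seg)
  expect_equal(fs_y$tf, fs$tf, tolerance = 1e-8)
  expect_equal(fs_y$le, fs$le, tolerance = 1e-8)
  expect_equal(fs_y$lpoe, fs$lpoe, tolerance = 1e-8)
  # a general rotation (about z) changes TF but not LE / LPOE
  ct_z <- transform_transfer(ct, R = rot_z(25))
  fs_z <- extract_features(ct_z, seg)
  expect_equal(fs_z$le, fs$le, tolerance = 1e-8)
  expect_equal(fs_z$lpoe, fs$lpoe, tolerance = 1e-8)
  expect_gt(abs(fs_z$tf - fs$tf), 5)
})

test_that("time-reversed sequences give identical angle means", {
  ct <- constant_pose_transfer(n = 150)
  ct$pelvis_x <- ramp_series()
  ct$spine_upper_x <- ct$pelvis_x + 150
  seg <- detect_phases(ct$pelvis_x, 30)
  fs <- extract_features(ct, seg)
  rev_idx <- rev(seq_len(nrow(ct)))
  ct_r <- ct
  for (col in setdiff(names(ct), "timestamp")) ct_r[[col]] <- ct[[col]][rev_idx]
  seg_r <- detect_phases(ct_r$pelvis_x, 30)
  fs_r <- extract_features(ct_r, seg_r)
  expect_equal(fs_r$tf, fs$tf, tolerance = 0.3)
  expect_equal(fs_r$le, fs$le, tolerance = 0.3)
  # reversed transfer runs in -x; displacement is still reported positive
  expect_equal(fs_r$dswp, fs$dswp, tolerance = 0.5)
})
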