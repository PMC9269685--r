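test_that("identical raters with real between-target variance give ICC 1", {
  m <- cbind(1:6, 1:6, 1:6)
  for (model in c("ICC_2_1", "ICC_3_1")) {
    r <- icc(m, model)
    expect_equal(r$icc, 1)
    expect_equal(r$category, "excellent")
  }
})

test_that("icc matches an independent aov mean-squares oracle to 1e-10", {
  set.seed(31)
  for (i in 1:20) {
    n <- sample(4:12, 1); k <- sample(2:5, 1)
    m <- matrix(rnorm(n * k, 50, 5), n, k) +
      rnorm(n, 0, 3) + rep(rnorm(k, 0, 2), each = n)
    for (model in c("ICC_2_1", "ICC_3_1")) {
      expect_equal(icc(m, model)$icc, oracle_icc(m, model),
                   tolerance = 1e-10)
    }
  }
})

test_that("icc point estimates and CIs agree with an external reference", {
  # reference values computed with pingouin 0.6.1 intraclass_corr on this
  # exact matrix (ICC(A,1) and ICC(C,1) rows)
  set.seed(42)
  m <- matrix(round(rnorm(24, 50, 8), 4), 8, 3)
  m[, 2] <- m[, 2] + 3
  r2 <- icc(m, "ICC_2_1")
  r3 <- icc(m, "ICC_3_1")
  expect_equal(r2$icc, 0.2144431117, tolerance = 1e-9)
  expect_equal(r3$icc, 0.2880237893, tolerance = 1e-9)
  expect_lt(abs(r2$ci_lower - -0.08), 0.005)
  expect_lt(abs(r2$ci_upper - 0.67), 0.005)
  expect_lt(abs(r3$ci_lower - -0.13), 0.005)
  expect_lt(abs(r3$ci_upper - 0.75), 0.005)
})

test_that("simulated variance components are recovered by ICC(2,1)", {
  # analytic ICC = 9 / (9 + 1) = 0.9
  set.seed(77)
  b <- rnorm(200, 0, 3)
  m <- cbind(b + rnorm(200), b + rnorm(200))
  r <- icc(m, "ICC_2_1")
  expect_lt(abs(r$icc - 0.9), 0.05)
})

test_that("a pure rater offset lowers absolute agreement but not consistency", {
  set.seed(13)
  b <- rnorm(40, 50, 5)
  m <- cbind(b + rnorm(40, 0, 1), b + rnorm(40, 0, 1) + 6)
  r2 <- icc(m, "ICC_2_1")
  r3 <- icc(m, "ICC_3_1")
  expect_gt(r3$icc, r2$icc)
  expect_gt(r3$icc, 0.8)
})

test_that("degenerate matrices are rejected with instructive errors", {
  expect_error(icc(matrix(5, 4, 3)), "zero total variance")
  expect_error(icc(matrix(c(1, NA, 3, 4), 2, 2)), "complete-case")
  expect_error(icc(matrix(1:3, 3, 1)), "at least 2")
})

test_that("ICC categories honour the published bands and boundaries", {
  expect_equal(categorize_icc(0.92), "excellent")
  expect_equal(categorize_icc(0.13), "poor")
  expect_equal(categorize_icc(0.80), "good")     # excellent is strictly > 0.8
  expect_equal(categorize_icc(0.81), "excellent")
  expect_equal(
    categorize_icc(c(-0.5, 0.2, 0.39, 0.4, 0.6, 0.79)),
    c("poor", "fair", "fair", "moderate", "good", "good"))
  # total and monotone
  grid <- seq(-1, 1, by = 0.01)
  cats <- categorize_icc(grid)
  levels_ord <- c("poor", "fair", "moderate", "good", "excellent")
  expect_true(all(diff(match(cats, levels_ord)) >= 0))
})

test_that("bland_altman reproduces hand-computed limits", {
  r <- bland_altman(c(1, 2, 3), c(2, 2, 2)) # d = -1, 0, 1
  expect_equal(r$m, 0)
  expect_equal(r$s, 1)
  expect_equal(r$infimum, -1.96)
  expect_equal(r$supremum, 1.96)
  expect_equal(r$within_fraction, 1)
  expect_true(r$interchangeable)
})

test_that("identical measurement series are trivially interchangeable", {
  a <- rnorm(20)
  r <- bland_altman(a, a)
  expect_equal(r$m, 0)
  expect_equal(r$s, 0)
  expect_equal(r$within_fraction, 1)
  expect_true(r$interchangeable)
})

test_that("Gaussian differences put about 95% of pairs inside the limits", {
  set.seed(500)
  a <- rnorm(1000); b <- rnorm(1000)
  r <- bland_altman(a, b)
  expect_lt(abs(r$within_fraction - 0.95), 0.02)
})

test_that("bland_altman rejects unequal lengths", {
  expect_error(bland_altman(1:5, 1:4), "length")
})

test_that("the reliability report mirrors the study's table structure", {
  set.seed(8)
  feats <- c("dswp", "lpoe", "le", "tf")
  rows <- expand.grid(subject_id = paste0("s", 1:7), trial = 1:10,
                      sensor = c("A", "B"), stringsAsFactors = FALSE)
  rows$trial_id <- paste0(rows$subject_id, "_t", rows$trial)
  subj_eff <- rnorm(7, 0, 5)
  for (f in feats) {
    base <- subj_eff[as.integer(sub("s", "", rows$subject_id))]
    rows[[f]] <- 50 + base + rnorm(nrow(rows), 0, 2)
  }
  rep <- reliability_report(rows)
  expect_equal(nrow(rep$intra), 4 * 2)   # 4 features x 2 sensors
  expect_equal(nrow(rep$inter), 4)       # 4 features x 1 sensor pair
  expect_length(rep$bland_altman, 4)
  expect_true(all(c("icc", "ci_lower", "ci_upper", "category",
                    "mean_a", "std_a", "mean_b", "std_b", "ba_m", "ba_s",
                    "ba_inf", "ba_sup", "ba_within", "interchangeable")
                  %in% names(rep$inter)))
  expect_true(all(rep$inter$ci_lower <= rep$inter$icc))
  expect_true(all(rep$inter$icc <= rep$inter$ci_upper))
  expect_true(all(!is.na(rep$intra$diff)))
})

test_that("two identical virtual sensors give perfect agreement everywhere", {
  set.seed(9)
  base <- expand.grid(subject_id = paste0("s", 1:5), trial = 1:4,
                      stringsAsFactors = FALSE)
  base$trial_id <- paste0(base$subject_id, "_t", base$trial)
  for (f in c("dswp", "lpoe", "le", "tf")) base[[f]] <- rnorm(nrow(base), 50, 5)
  two <- rbind(cbind(sensor = "A", base), cbind(sensor = "B", base))
  rep <- reliability_report(two)
  expect_true(all(abs(rep$inter$icc - 1) < 1e-12))
  expect_true(all(rep$inter$ba_m == 0 & rep$inter$ba_s == 0))
  expect_true(all(rep$inter$interchangeable))
})

test_that("a fixed +5 deg offset shows up in BA and lowers ICC(2,1)", {
  set.seed(10)
  base <- expand.grid(subject_id = paste0("s", 1:6), trial = 1:5,
                      stringsAsFactors = FALSE)
  base$trial_id <- paste0(base$subject_id, "_t", base$trial)
  subj <- rnorm(6, 0, 6)
  for (f in c("dswp", "lpoe", "le", "tf")) {
    base[[f]] <- 40 + subj[as.integer(sub("s", "", base$subject_id))] +
      rnorm(nrow(base), 0, 1)
  }
  b <- base; b$tf <- b$tf + 5
  two <- rbind(cbind(sensor = "A", base), cbind(sensor = "B", b))
  rep <- reliability_report(two)
  tf_row <- rep$inter[rep$inter$feature == "tf", ]
  expect_equal(tf_row$ba_m, -5, tolerance = 1e-9)
  tf_intra <- rep$intra[rep$intra$feature == "tf", ]
  expect_true(all(tf_intra$icc > tf_row$icc))
})

test_that("unequal trial counts are truncated with a warning", {
  set.seed(12)
  base <- data.frame(
    sensor = "A",
    subject_id = rep(c("s1", "s2", "s3"), times = c(4, 3, 4)),
    stringsAsFactors = FALSE
  )
  base$trial_id <- paste0(base$subject_id, "_t", unlist(lapply(c(4, 3, 4), seq_len)))
  for (f in c("dswp", "lpoe", "le", "tf")) base[[f]] <- rnorm(nrow(base), 50, 5)
  expect_warning(rep <- reliability_report(base), "truncating")
  expect_equal(unique(rep$intra$n_trials), 3)
})

test_that("reports serialize to CSV and JSON", {
  set.seed(14)
  base <- expand.grid(subject_id = paste0("s", 1:4), trial = 1:3,
                      stringsAsFactors = FALSE)
  base$trial_id <- paste0(base$subject_id, "_t", base$trial)
  for (f in c("dswp", "lpoe", "le", "tf")) base[[f]] <- rnorm(nrow(base), 50, 5)
  two <- rbind(cbind(sensor = "A", base), cbind(sensor = "B", base))
  two$dswp <- two$dswp + rnorm(nrow(two), 0, 0.1)
  rep <- reliability_report(two)
  dir <- withr::local_tempdir()
  write_reliability_report(rep, dir)
  expect_true(file.exists(file.path(dir, "reliability_intra.csv")))
  expect_true(file.exists(file.path(dir, "reliability_inter.csv")))
  j <- jsonlite::read_json(file.path(dir, "reliability.json"))
  expect_named(j, c("intra", "inter"))
})
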