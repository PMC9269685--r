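#' Single-measure intraclass correlation from a two-way ANOVA
#'
#' Computes a single-measure ICC for an `n x k` measurement matrix (rows =
#' targets: subjects or trials; columns = raters: repeated trials or
#' sensors) from the two-way ANOVA mean squares: between-targets `MSR`,
#' between-raters `MSC` and residual `MSE`.
#'
#' * `ICC_2_1` -- two-way random effects, absolute agreement, single
#'   measure: `(MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))`, with the
#'   McGraw-Wong F-based confidence interval (Satterthwaite degrees of
#'   freedom). Used for inter-sensor reliability: a systematic offset
#'   between sensors lowers it.
#' * `ICC_3_1` -- two-way mixed effects, single measure, consistency form:
#'   `(MSR - MSE) / (MSR + (k-1) MSE)`, with the exact F interval. Used for
#'   intra-sensor (test-retest) reliability; column offsets do not affect
#'   it, so on data with a pure rater offset `ICC_3_1 >= ICC_2_1`.
#'
#' @param values Numeric `n x k` matrix, complete (no `NA`), `n >= 2`,
#'   `k >= 2`.
#' @param model `"ICC_2_1"` or `"ICC_3_1"`.
#' @param conf_level Confidence level for the interval (default 0.95).
#' @return An `icc_result` list: `icc`, `ci_lower`, `ci_upper`, `model`,
#'   `category` (see [categorize_icc()]), `n`, `k` and the mean squares.
#' @export
icc <- function(values, model = c("ICC_2_1", "ICC_3_1"), conf_level = 0.95) {
  model <- match.arg(model)
  values <- as.matrix(values)
  if (anyNA(values)) {
    stop("measurement matrix has missing cells; apply complete-case ",
         "filtering upstream", call. = FALSE)
  }
  n <- nrow(values); k <- ncol(values)
  if (n < 2 || k < 2) {
    stop("need at least 2 targets and 2 raters", call. = FALSE)
  }
  grand <- mean(values)
  row_means <- rowMeans(values)
  col_means <- colMeans(values)
  ssr <- k * sum((row_means - grand)^2)
  ssc <- n * sum((col_means - grand)^2)
  sst <- sum((values - grand)^2)
  sse <- sst - ssr - ssc
  sse <- max(sse, 0) # guard tiny negative rounding
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  if (sst == 0) {
    stop("undefined ICC: measurement matrix has zero total variance",
         call. = FALSE)
  }
  alpha <- 1 - conf_level
  if (model == "ICC_3_1") {
    denom <- msr + (k - 1) * mse
    if (denom == 0) stop("undefined ICC: zero variance", call. = FALSE)
    est <- (msr - mse) / denom
    if (mse == 0) {
      ci <- c(est, est)
    } else {
      f_obs <- msr / mse
      df1 <- n - 1; df2 <- (n - 1) * (k - 1)
      fl <- f_obs / stats::qf(1 - alpha / 2, df1, df2)
      fu <- f_obs * stats::qf(1 - alpha / 2, df2, df1)
      ci <- c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1))
    }
  } else {
    denom <- msr + (k - 1) * mse + (k / n) * (msc - mse)
    if (denom == 0) stop("undefined ICC: zero variance", call. = FALSE)
    est <- (msr - mse) / denom
    if (mse == 0 && msc == 0) {
      ci <- c(est, est)
    } else {
      r <- est
      a <- (k * r) / (n * (1 - r))
      b <- 1 + (k * r * (n - 1)) / (n * (1 - r))
      v <- (a * msc + b * mse)^2 /
        ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
      f1 <- stats::qf(1 - alpha / 2, n - 1, v)
      f2 <- stats::qf(1 - alpha / 2, v, n - 1)
      lower <- n * (msr - f1 * mse) /
        (f1 * (k * msc + (k * n - k - n) * mse) + n * msr)
      upper <- n * (f2 * msr - mse) /
        (k * msc + (k * n - k - n) * mse + n * f2 * msr)
      ci <- c(lower, upper)
    }
  }
  ci[1] <- min(ci[1], est); ci[2] <- max(ci[2], est)
  structure(
    list(
      icc = est, ci_lower = ci[1], ci_upper = ci[2], model = model,
      category = categorize_icc(est), conf_level = conf_level,
      n = n, k = k, msr = msr, msc = msc, mse = mse
    ),
    class = "icc_result"
  )
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("<icc_result> %s = %.3f [%.3f, %.3f] (%s; n=%d targets, k=%d raters)\n",
              x$model, x$icc, x$ci_lower, x$ci_upper, x$category, x$n, x$k))
  invisible(x)
}

#' Categorize an ICC value
#'
#' Category bands: excellent (ICC > 0.8), good (0.6-0.8, upper bound
#' included since "excellent" is strictly above 0.8), moderate
#' \[0.4, 0.6), fair \[0.2, 0.4), poor (< 0.2). Total, monotone step
#' function.
#'
#' @param icc Finite ICC value (vectorized).
#' @return Character vector of categories.
#' @export
categorize_icc <- function(icc) {
  stopifnot(all(is.finite(icc)))
  # lower bounds inclusive; "excellent" alone is strict (> 0.8), so 0.8 is
  # still "good"
  ifelse(icc > 0.8, "excellent",
    ifelse(icc >= 0.6, "good",
      ifelse(icc >= 0.4, "moderate",
        ifelse(icc >= 0.2, "fair", "poor"))))
}

#' Bland-Altman agreement between two paired measurement series
#'
#' Limits of agreement on the paired differences `d = a - b`: the infimum
#' `m - 1.96 s` and supremum `m + 1.96 s`, where `m` is the mean difference
#' and `s` the sample standard deviation (n-1). Under the Gaussian
#' hypothesis two methods are deemed interchangeable when at least 95% of
#' the differences fall within the limits.
#'
#' @param a,b Equal-length numeric vectors (length >= 3) of the same
#'   feature measured by two methods on the same trials.
#' @param limit_multiplier Multiplier of `s` for the limits (default 1.96).
#' @return A `bland_altman_result` list: `m`, `s`, `infimum`, `supremum`,
#'   `within_fraction`, `interchangeable`, and `data` (per-pair mean and
#'   difference, for plotting).
#' @export
bland_altman <- function(a, b, limit_multiplier = 1.96) {
  if (length(a) != length(b)) {
    stop("paired series have different lengths", call. = FALSE)
  }
  if (length(a) < 3) stop("need at least 3 pairs", call. = FALSE)
  d <- a - b
  m <- mean(d)
  s <- stats::sd(d)
  infimum <- m - limit_multiplier * s
  supremum <- m + limit_multiplier * s
  within <- mean(d >= infimum & d <= supremum)
  structure(
    list(
      m = m, s = s, infimum = infimum, supremum = supremum,
      within_fraction = within, interchangeable = within >= 0.95,
      n = length(d),
      data = data.frame(mean = (a + b) / 2, difference = d)
    ),
    class = "bland_altman_result"
  )
}

#' @export
print.bland_altman_result <- function(x, ...) {
  cat(sprintf(
    "<bland_altman> m = %.3f, s = %.3f, limits [%.3f, %.3f], %.1f%% within (%s)\n",
    x$m, x$s, x$infimum, x$supremum, 100 * x$within_fraction,
    if (x$interchangeable) "interchangeable" else "not interchangeable"))
  invisible(x)
}

#' Bland-Altman plot
#'
#' @param ba A [bland_altman()] result.
#' @param ... Passed to [plot()].
#' @export
plot_bland_altman <- function(ba, ...) {
  plot(ba$data$mean, ba$data$difference,
       xlab = "mean of methods", ylab = "difference (a - b)", ...)
  graphics::abline(h = c(ba$infimum, ba$m, ba$supremum),
                   lty = c(2, 1, 2), col = c("red", "black", "red"))
  invisible(ba)
}

#' Full reliability report over per-trial features
#'
#' Reproduces the structure of a sensor-comparison reliability analysis on a
#' tidy feature table: per feature, the intra-sensor (test-retest) ICC(3,1)
#' per sensor (targets = subjects, raters = trial repetitions; subjects are
#' truncated to the common minimum trial count with a warning), the
#' inter-sensor ICC(2,1) (targets = pooled trials, raters = sensors,
#' complete-case pairing), per-sensor mean and SD, and the Bland-Altman
#' limits of agreement for each sensor pair.
#'
#' @param features Data frame with columns `sensor`, `subject_id`,
#'   `trial_id` and one column per feature.
#' @param feature_cols Feature column names (default
#'   `c("dswp", "lpoe", "le", "tf")`).
#' @param conf_level Confidence level for ICC intervals.
#' @return A `reliability_report` list with data frames `intra` (feature,
#'   sensor, icc, ci bounds, category, mean, sd, plus a `diff` column of
#'   pairwise ICC differences when exactly two sensors are present),
#'   `inter` (one row per feature and sensor pair with the spec'd columns
#'   feature, model, icc, ci_lower, ci_upper, category, mean_a, std_a,
#'   mean_b, std_b, ba_m, ba_s, ba_inf, ba_sup, ba_within, interchangeable),
#'   and `bland_altman` (the underlying result objects keyed
#'   `feature:sensor_a:sensor_b`).
#' @export
reliability_report <- function(features,
                               feature_cols = c("dswp", "lpoe", "le", "tf"),
                               conf_level = 0.95) {
  stopifnot(all(c("sensor", "subject_id", "trial_id") %in% names(features)),
            all(feature_cols %in% names(features)))
  sensors <- unique(features$sensor)
  if (length(sensors) < 1) stop("no sensors in feature table", call. = FALSE)

  intra <- list()
  for (s in sensors) {
    fs <- features[features$sensor == s, ]
    counts <- table(fs$subject_id)
    k <- min(counts)
    if (k < 2 || length(counts) < 2) {
      warning("sensor ", s, ": fewer than 2 repeated trials per subject ",
              "or fewer than 2 subjects; intra-sensor section omitted")
      next
    }
    if (length(unique(counts)) > 1) {
      warning("sensor ", s, ": unequal trial counts per subject; ",
              "truncating to the common minimum (", k, ")")
    }
    for (f in feature_cols) {
      m <- t(vapply(split(fs[[f]], fs$subject_id),
                    function(v) v[seq_len(k)], numeric(k)))
      if (anyNA(m)) {
        warning("sensor ", s, ", feature ", f,
                ": missing values; intra-sensor ICC skipped")
        next
      }
      r <- icc(m, "ICC_3_1", conf_level)
      intra[[length(intra) + 1]] <- data.frame(
        feature = f, sensor = s, model = "ICC_3_1",
        icc = r$icc, ci_lower = r$ci_lower, ci_upper = r$ci_upper,
        category = r$category,
        mean = mean(m), sd = stats::sd(as.vector(m)),
        n_subjects = nrow(m), n_trials = k,
        stringsAsFactors = FALSE
      )
    }
  }
  intra <- if (length(intra)) do.call(rbind, intra) else NULL
  if (!is.null(intra) && length(unique(intra$sensor)) == 2) {
    wide <- split(intra, intra$feature)
    intra$diff <- NA_real_
    for (f in names(wide)) {
      if (nrow(wide[[f]]) == 2) {
        intra$diff[intra$feature == f] <- abs(diff(wide[[f]]$icc))
      }
    }
  }

  inter <- list(); ba_store <- list()
  if (length(sensors) >= 2) {
    pairs <- utils::combn(sensors, 2, simplify = FALSE)
    key <- function(df) paste(df$subject_id, df$trial_id, sep = "\r")
    for (p in pairs) {
      fa <- features[features$sensor == p[1], ]
      fb <- features[features$sensor == p[2], ]
      common <- intersect(key(fa), key(fb))
      fa <- fa[match(common, key(fa)), ]
      fb <- fb[match(common, key(fb)), ]
      for (f in feature_cols) {
        ok <- stats::complete.cases(fa[[f]], fb[[f]])
        a <- fa[[f]][ok]; b <- fb[[f]][ok]
        if (length(a) < 3) {
          warning("pair ", p[1], "/", p[2], ", feature ", f,
                  ": fewer than 3 complete trials; skipped")
          next
        }
        r <- icc(cbind(a, b), "ICC_2_1", conf_level)
        ba <- bland_altman(a, b)
        ba_store[[paste(f, p[1], p[2], sep = ":")]] <- ba
        inter[[length(inter) + 1]] <- data.frame(
          feature = f, sensor_a = p[1], sensor_b = p[2], model = "ICC_2_1",
          icc = r$icc, ci_lower = r$ci_lower, ci_upper = r$ci_upper,
          category = r$category,
          mean_a = mean(a), std_a = stats::sd(a),
          mean_b = mean(b), std_b = stats::sd(b),
          ba_m = ba$m, ba_s = ba$s, ba_inf = ba$infimum,
          ba_sup = ba$supremum, ba_within = ba$within_fraction,
          interchangeable = ba$interchangeable,
          n_trials = length(a),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  inter <- if (length(inter)) do.call(rbind, inter) else NULL

  structure(
    list(intra = intra, inter = inter, bland_altman = ba_store,
         feature_cols = feature_cols, sensors = sensors),
    class = "reliability_report"
  )
}

#' @export
print.reliability_report <- function(x, ...) {
  cat("<reliability_report>", length(x$sensors), "sensor(s):",
      paste(x$sensors, collapse = ", "), "\n")
  if (!is.null(x$intra)) {
    cat("-- intra-sensor ICC(3,1) --\n")
    print(x$intra, row.names = FALSE)
  }
  if (!is.null(x$inter)) {
    cat("-- inter-sensor ICC(2,1) + Bland-Altman --\n")
    print(x$inter, row.names = FALSE)
  }
  invisible(x)
}

#' Write a reliability report to CSV and JSON
#'
#' @param report A [reliability_report()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_reliability_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(report$intra)) {
    utils::write.csv(report$intra, file.path(dir, "reliability_intra.csv"),
                     row.names = FALSE)
  }
  if (!is.null(report$inter)) {
    utils::write.csv(report$inter, file.path(dir, "reliability_inter.csv"),
                     row.names = FALSE)
  }
  jsonlite::write_json(
    list(intra = report$intra, inter = report$inter),
    file.path(dir, "reliability.json"),
    dataframe = "rows", na = "null", auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
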