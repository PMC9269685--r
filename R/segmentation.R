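#' Zero-phase low-pass Butterworth filter
#'
#' Filters a kinematic time series with an order-`order` Butterworth low-pass
#' filter applied forward and backward (`signal::filtfilt`), so the output is
#' zero-phase: phase events such as plateau edges are not lagged. Used only
#' for phase detection; feature values are always computed on raw data.
#'
#' @param x Numeric series (mm). Must be complete; interpolate missing
#'   samples first (see [fill_gaps()]).
#' @param rate Sampling rate, Hz. Must exceed `2 * cutoff`.
#' @param cutoff Cutoff frequency, Hz. Default 15.
#' @param order Filter order, default 4.
#' @param zero_phase Apply forward-backward (`TRUE`, default) or single-pass.
#' @return Filtered series, same length as `x`.
#' @export
lowpass_filter <- function(x, rate, cutoff = 15, order = 4,
                           zero_phase = TRUE) {
  if (anyNA(x)) stop("series contains missing samples; interpolate first",
                     call. = FALSE)
  if (length(x) <= 3 * order) {
    stop("series too short to filter (need > ", 3 * order, " samples)",
         call. = FALSE)
  }
  if (rate <= 2 * cutoff) {
    stop("sampling rate must exceed twice the cutoff frequency",
         call. = FALSE)
  }
  bf <- signal::butter(order, cutoff / (rate / 2), type = "low")
  if (zero_phase) {
    filtfilt_refl(bf$b, bf$a, x)
  } else {
    as.numeric(signal::filter(bf, x))
  }
}

# steady-state initial filter state for a unit step input (direct form II
# transposed), so the transient of a constant segment vanishes exactly
lfilter_zi <- function(b, a) {
  n <- max(length(a), length(b))
  b <- c(b, rep(0, n - length(b)))
  a <- c(a, rep(0, n - length(a)))
  b <- b / a[1]; a <- a / a[1]
  comp <- rbind(-a[2:n], cbind(diag(n - 2), rep(0, n - 2)))
  iminus <- diag(n - 1) - t(comp)
  rhs <- b[2:n] - a[2:n] * b[1]
  solve(iminus, rhs)
}

# direct form II transposed IIR filter with explicit initial state
iir_filter <- function(b, a, x, zi) {
  n <- max(length(a), length(b))
  b <- c(b, rep(0, n - length(b))) / a[1]
  a <- c(a, rep(0, n - length(a))) / a[1]
  z <- zi
  y <- numeric(length(x))
  for (i in seq_along(x)) {
    y[i] <- b[1] * x[i] + z[1]
    if (n > 2) {
      for (j in seq_len(n - 2)) {
        z[j] <- b[j + 1] * x[i] + z[j + 1] - a[j + 1] * y[i]
      }
    }
    z[n - 1] <- b[n] * x[i] - a[n] * y[i]
  }
  y
}

# forward-backward filtering with odd-reflection end padding and
# steady-state initial conditions (the classic filtfilt edge treatment)
filtfilt_refl <- function(b, a, x) {
  nx <- length(x)
  n <- max(length(a), length(b))
  nfact <- 3 * (n - 1)
  if (nx <= nfact) stop("series too short to filter", call. = FALSE)
  pre <- 2 * x[1] - x[seq(nfact + 1, 2)]
  post <- 2 * x[nx] - x[seq(nx - 1, nx - nfact)]
  ext <- c(pre, x, post)
  zi <- lfilter_zi(b, a)
  y <- iir_filter(b, a, ext, zi * ext[1])
  y <- rev(iir_filter(b, a, rev(y), zi * y[length(y)]))
  y[(nfact + 1):(nfact + nx)]
}

#' Linearly interpolate missing samples
#'
#' @param x Numeric series with possible `NA` runs.
#' @param rate Sampling rate (Hz), used for the maximum tolerated gap.
#' @param max_gap Longest tolerated missing run, seconds (default 0.5 s).
#'   A longer run aborts with an error: such trials must fail loudly rather
#'   than be silently reconstructed.
#' @return The series with `NA`s linearly interpolated (edge `NA`s held at
#'   the nearest observed value).
#' @export
fill_gaps <- function(x, rate, max_gap = 0.5) {
  if (!anyNA(x)) return(x)
  if (all(is.na(x))) stop("series has no observed samples", call. = FALSE)
  runs <- rle(is.na(x))
  if (max(runs$lengths[runs$values]) > max_gap * rate) {
    stop(sprintf(
      "missing run longer than %.2f s; trial cannot be segmented reliably",
      max_gap), call. = FALSE)
  }
  idx <- seq_along(x)
  stats::approx(idx[!is.na(x)], x[!is.na(x)], xout = idx, rule = 2)$y
}

#' Detect the lift phase of a transfer from the pelvis x-trajectory
#'
#' A sitting-pivot transfer shows three phases in the pelvis position along
#' the transfer axis: an initial plateau (sitting on the first surface), a
#' rising "lift" segment, and a final plateau (landed). The lift start is the
#' end of the first plateau -- the last point still at the plateau level
#' before the rise -- and the lift end is the first point at the landing
#' level.
#'
#' The series is gap-filled, sign-normalized (transfers in the -x direction
#' are negated), and low-pass filtered (zero phase). Plateau and landing
#' levels are estimated as medians of the frames in the bottom / top 20% band
#' of the displacement, which is robust to jitter; the phase boundaries are
#' then the last/first crossings of a noise-adaptive threshold (3x the MAD of
#' the plateau residuals, floored at 0.2% of the rise) above/below those
#' levels. Detection is invariant to amplitude scaling and equivariant to
#' time shifts.
#'
#' @param pelvis_x Pelvis x-position series, mm (raw; may contain `NA`s).
#' @param rate Sampling rate, Hz.
#' @param cutoff Butterworth cutoff, Hz (default 15). Internally clamped to
#'   `0.45 * rate` so that 30 Hz recordings can be processed with the default
#'   cutoff, which sits at the Nyquist frequency.
#' @param order Filter order (default 4).
#' @param zero_phase Zero-phase filtering (default `TRUE`).
#' @param noise_floor Minimum net displacement (mm) for the series to count
#'   as a transfer; default 100.
#' @param band_frac Fraction of the rise defining the plateau/landing bands
#'   for level estimation (default 0.2).
#' @param min_threshold_frac Floor of the edge-crossing threshold as a
#'   fraction of the rise (default 0.002).
#' @return A `phase_segmentation` list: `lift_start_idx`, `lift_end_idx`
#'   (1-based frame indices into the input series), `filtered_x` (the
#'   filtered, sign-normalized series kept for audit), `direction` (+1/-1),
#'   `net_displacement` (mm, always positive), `plateau_level`, `top_level`.
#' @export
detect_phases <- function(pelvis_x, rate, cutoff = 15, order = 4,
                          zero_phase = TRUE, noise_floor = 100,
                          band_frac = 0.2, min_threshold_frac = 0.002) {
  x <- fill_gaps(as.numeric(pelvis_x), rate)
  n <- length(x)
  if (n <= 3 * order) {
    stop("series too short to segment", call. = FALSE)
  }
  # transfers toward -x are analysed on the negated series
  head_lvl <- stats::median(x[seq_len(max(3, ceiling(n * 0.1)))])
  tail_lvl <- stats::median(x[seq(n - max(3, ceiling(n * 0.1)) + 1, n)])
  direction <- if (tail_lvl >= head_lvl) 1 else -1
  x <- direction * x

  eff_cutoff <- min(cutoff, 0.45 * rate)
  xf <- lowpass_filter(x, rate, eff_cutoff, order, zero_phase)

  lo <- min(xf); hi <- max(xf)
  rise <- hi - lo
  if (rise < noise_floor) {
    stop("no transfer detected: net displacement ",
         sprintf("%.1f", rise), " mm below the ", noise_floor, " mm floor",
         call. = FALSE)
  }
  # a strictly monotone trajectory has no plateaus to delimit a lift
  # (checked on the unfiltered series: filter edge transients are not motion)
  if (all(diff(x) > 0) || all(diff(x) < 0)) {
    stop("no plateau regions found: series is strictly monotone",
         call. = FALSE)
  }
  half <- (lo + hi) / 2
  half_idx <- which(xf >= half)[1]

  pre <- seq_len(half_idx - 1)
  post <- seq(half_idx, n)
  low_band <- pre[xf[pre] <= lo + band_frac * rise]
  high_band <- post[xf[post] >= hi - band_frac * rise]
  if (length(low_band) < 2 || length(high_band) < 2) {
    stop("no plateau regions found around the rise", call. = FALSE)
  }
  plateau_level <- stats::median(xf[low_band])
  top_level <- stats::median(xf[high_band])
  sigma <- stats::mad(xf[low_band] - plateau_level)
  threshold <- max(3 * sigma, min_threshold_frac * rise)

  below <- pre[xf[pre] <= plateau_level + threshold]
  above <- post[xf[post] >= top_level - threshold]
  if (length(below) == 0 || length(above) == 0) {
    stop("no plateau regions found around the rise", call. = FALSE)
  }
  lift_start <- max(below)
  lift_end <- min(above)
  if (lift_end <= lift_start) {
    stop("degenerate lift phase (end before start)", call. = FALSE)
  }
  structure(
    list(
      lift_start_idx = lift_start,
      lift_end_idx = lift_end,
      filtered_x = xf,
      direction = direction,
      net_displacement = rise,
      plateau_level = plateau_level,
      top_level = top_level,
      rate = rate
    ),
    class = "phase_segmentation"
  )
}

#' @export
print.phase_segmentation <- function(x, ...) {
  cat("<phase_segmentation> lift frames",
      x$lift_start_idx, "-", x$lift_end_idx,
      sprintf("(%.2f-%.2f s), net displacement %.1f mm, direction %+d\n",
              (x$lift_start_idx - 1) / x$rate, (x$lift_end_idx - 1) / x$rate,
              x$net_displacement, x$direction))
  invisible(x)
}

#' Plot a segmented pelvis trajectory
#'
#' Draws the filtered pelvis x-trajectory with the detected pre-lift, lift
#' and landing phases annotated.
#'
#' @param seg A [detect_phases()] result.
#' @param ... Passed to [plot()].
#' @export
plot_segmentation <- function(seg, ...) {
  n <- length(seg$filtered_x)
  t <- (seq_len(n) - 1) / seg$rate
  plot(t, seg$filtered_x, type = "l", xlab = "time (s)",
       ylab = "pelvis x (mm, filtered)", ...)
  graphics::abline(v = t[c(seg$lift_start_idx, seg$lift_end_idx)],
                   lty = 2, col = "red")
  graphics::text(t[seg$lift_start_idx], seg$plateau_level, "lift start",
                 pos = 4, col = "red", cex = 0.8)
  graphics::text(t[seg$lift_end_idx], seg$top_level, "lift end",
                 pos = 2, col = "red", cex = 0.8)
  invisible(seg)
}
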