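# Open-loop pursuit estimation: low-pass filtering of gaze traces, the
# post-saccadic analysis window, orthogonal-regression direction, mean-vector
# speed, and the presaccadic pursuit screen.

#' Low-pass filter a gaze trace
#'
#' Applies a 100-tap windowed (Hamming) FIR low-pass filter with a 40-Hz
#' cutoff, forward, and compensates the 49.5-sample group delay by shifting
#' 50 samples (the residual half-sample shift is irrelevant for direction and
#' speed estimates taken over 80-ms windows).  Samples within half a filter
#' length of either end of the recording become `NA`.
#'
#' @param gaze Data frame `t_ms`, `x`, `y` at a uniform sampling rate.
#' @param n_taps Filter length (default 100).
#' @param cutoff_hz Cutoff frequency, Hz.
#' @return `gaze` with filtered `x`, `y` (edges `NA`).
#' @export
lowpass_filter <- function(gaze, n_taps = 100, cutoff_hz = 40) {
  n <- nrow(gaze)
  if (n < n_taps) stop("recording shorter than the filter")
  dt <- gaze$t_ms[2] - gaze$t_ms[1]
  fs <- 1000 / dt
  h <- signal::fir1(n_taps - 1, cutoff_hz / (fs / 2), type = "low")
  h <- h / sum(h)                      # unit DC gain
  delay <- round((n_taps - 1) / 2)
  apply1 <- function(x) {
    y <- stats::filter(x, h, method = "convolution", sides = 1)
    out <- rep(NA_real_, n)
    idx <- seq_len(n - delay)
    out[idx] <- y[idx + delay]
    out
  }
  gaze$x <- apply1(gaze$x)
  gaze$y <- apply1(gaze$y)
  gaze
}

#' Post-saccadic analysis window
#'
#' Samples from `window[1]` to `window[2]` ms after the saccade offset
#' (default 20-100 ms; the first 20 ms are excluded to avoid contamination by
#' inaccuracies in offset identification).
#'
#' @param gaze Data frame `t_ms`, `x`, `y` (typically filtered).
#' @param saccade One-row event with `offset_t`.
#' @param window Window relative to saccade offset, ms.
#' @return The slice of `gaze` inside the window.
#' @export
postsaccadic_window <- function(gaze, saccade, window = c(20, 100)) {
  t0 <- saccade$offset_t + window[1]
  t1 <- saccade$offset_t + window[2]
  if (max(gaze$t_ms) < t1)
    stop("short-trial: recording ends before the pursuit window")
  sl <- gaze[gaze$t_ms >= t0 & gaze$t_ms <= t1, , drop = FALSE]
  if (anyNA(sl$x) || anyNA(sl$y))
    stop("short-trial: pursuit window contains unfiltered or missing samples")
  sl
}

#' Pursuit direction by orthogonal regression
#'
#' Orientation of the first principal axis of the demeaned positions; the
#' sign is chosen so the direction points from the mean of the temporally
#' earlier half of the window to the mean of the later half.
#'
#' @param slice Gaze slice (`t_ms`, `x`, `y`), at least 10 samples.
#' @return Direction in degrees.
#' @export
pursuit_direction <- function(slice) {
  if (nrow(slice) < 10) stop("at least 10 samples are required")
  x <- slice$x - mean(slice$x)
  y <- slice$y - mean(slice$y)
  cv <- stats::cov(cbind(x, y))
  if (sum(diag(cv)) < .Machine$double.eps)
    stop("degenerate slice: zero spatial variance")
  ax <- eigen(cv, symmetric = TRUE)$vectors[, 1]
  half <- nrow(slice) %/% 2
  early <- c(mean(slice$x[1:half]), mean(slice$y[1:half]))
  late <- c(mean(slice$x[(half + 1):nrow(slice)]),
            mean(slice$y[(half + 1):nrow(slice)]))
  if (sum(ax * (late - early)) < 0) ax <- -ax
  wrap_angle(rad2deg(atan2(ax[2], ax[1])))
}

#' Pursuit speed as the norm of the time-averaged velocity
#'
#' Positions are differentiated (first differences over the sampling step),
#' the velocity vector is averaged over the whole window, and its Euclidean
#' norm is returned.
#'
#' @param slice Gaze slice (`t_ms`, `x`, `y`), at least 2 samples.
#' @return Speed in dva/s.
#' @export
pursuit_speed <- function(slice) {
  if (nrow(slice) < 2) stop("at least 2 samples are required")
  dts <- diff(slice$t_ms) / 1000
  vx <- mean(diff(slice$x) / dts)
  vy <- mean(diff(slice$y) / dts)
  sqrt(vx^2 + vy^2)
}

#' Post-saccadic pursuit estimate for one trial
#'
#' @param gaze_f Filtered gaze trace.
#' @param saccade One-row event with `offset_t`.
#' @param envelope_speed Stimulus speed, dva/s (for the gain).
#' @param window Analysis window relative to saccade offset, ms.
#' @return List with `direction` (deg), `speed` (dva/s), `gain`, `window`,
#'   `n_samples`.
#' @export
pursuit_estimate <- function(gaze_f, saccade, envelope_speed = 12,
                             window = c(20, 100)) {
  sl <- postsaccadic_window(gaze_f, saccade, window)
  sp <- pursuit_speed(sl)
  list(direction = pursuit_direction(sl), speed = sp,
       gain = sp / envelope_speed, window = window, n_samples = nrow(sl))
}

#' Presaccadic pursuit estimate
#'
#' Gaze velocity in the interval from 80 ms to 20 ms before saccade onset,
#' returned only when its speed exceeds the mean plus two standard deviations
#' of the per-sample gaze speed in a baseline interval (the 300 ms before
#' target onset); otherwise the trial is flagged sub-threshold.
#'
#' @param gaze_f Filtered gaze trace.
#' @param saccade One-row event with `onset_t`.
#' @param target_onset_t Target onset time, ms.
#' @param window Window relative to saccade onset, ms (negative).
#' @return List with `above_threshold` (logical), `speed`, `threshold`, and
#'   (when above threshold) `direction`.
#' @export
presaccadic_pursuit <- function(gaze_f, saccade, target_onset_t = 0,
                                window = c(-80, -20)) {
  base <- gaze_f[gaze_f$t_ms >= target_onset_t - 300 &
                   gaze_f$t_ms < target_onset_t, , drop = FALSE]
  base <- base[!is.na(base$x) & !is.na(base$y), , drop = FALSE]
  if (nrow(base) < 10) stop("missing baseline interval")
  dts <- diff(base$t_ms) / 1000
  bs <- sqrt((diff(base$x) / dts)^2 + (diff(base$y) / dts)^2)
  thr <- mean(bs) + 2 * stats::sd(bs)
  sl <- gaze_f[gaze_f$t_ms >= saccade$onset_t + window[1] &
                 gaze_f$t_ms <= saccade$onset_t + window[2], , drop = FALSE]
  sl <- sl[!is.na(sl$x) & !is.na(sl$y), , drop = FALSE]
  if (nrow(sl) < 10) stop("presaccadic window unavailable")
  sp <- pursuit_speed(sl)
  if (sp > thr)
    list(above_threshold = TRUE, speed = sp, threshold = thr,
         direction = pursuit_direction(sl))
  else
    list(above_threshold = FALSE, speed = sp, threshold = thr,
         direction = NA_real_)
}
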