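# Eye velocity computation, velocity-threshold saccade detection, and the
# sequential trial-level inclusion rules.

#' Saccade detection configuration
#'
#' @param velocity_window Moving-average window for velocity smoothing,
#'   samples.
#' @param lambda Multiplier of the median-based velocity spread that sets the
#'   elliptic detection threshold.
#' @param min_duration_ms Minimum above-threshold duration for an event.
#' @param min_separation_ms Events closer than this are merged.
#' @return A list of class `"detection_config"`.
#' @export
detection_config <- function(velocity_window = 5, lambda = 6,
                             min_duration_ms = 6, min_separation_ms = 20) {
  stopifnot(lambda > 1, min_duration_ms >= 2, velocity_window >= 1)
  structure(list(velocity_window = velocity_window, lambda = lambda,
                 min_duration_ms = min_duration_ms,
                 min_separation_ms = min_separation_ms),
            class = "detection_config")
}

# Centered moving average with truncated windows at the ends; NA propagates.
moving_average <- function(x, k) {
  if (k <= 1) return(x)
  n <- length(x)
  half <- floor(k / 2)
  i <- seq_len(n)
  lo <- pmax(1L, i - half); hi <- pmin(n, i + half)
  if (anyNA(x)) {
    bad <- is.na(x)
    x0 <- x; x0[bad] <- 0
    S <- c(0, cumsum(x0))
    B <- c(0, cumsum(bad))
    out <- (S[hi + 1] - S[lo]) / (hi - lo + 1)
    out[(B[hi + 1] - B[lo]) > 0] <- NA_real_
    out
  } else {
    S <- c(0, cumsum(x))
    (S[hi + 1] - S[lo]) / (hi - lo + 1)
  }
}

#' 2D eye velocity
#'
#' Symmetric-difference velocity over +/-2 samples (`(x[n+2] + x[n+1] -
#' x[n-1] - x[n-2]) / (6 dt)`), then smoothed with a moving average over
#' `velocity_window` samples.  The first and last two samples copy the
#' nearest interior estimate; windows are truncated at the ends.  Missing
#' samples propagate as missing.
#'
#' @param gaze Data frame with columns `t_ms`, `x`, `y`, uniformly sampled.
#' @param cfg A [detection_config()].
#' @return Data frame `t_ms`, `vx`, `vy` in dva/s.
#' @export
compute_velocity <- function(gaze, cfg = detection_config()) {
  n <- nrow(gaze)
  if (n < 5) stop("at least 5 samples are required")
  dt <- diff(gaze$t_ms)
  if (max(abs(dt - dt[1])) > 1e-6 * dt[1] + 1e-9)
    stop("non-uniform timestamps beyond tolerance")
  dts <- dt[1] / 1000                                  # s
  sym_diff <- function(x) {
    v <- rep(NA_real_, n)
    v[3:(n - 2)] <- (x[5:n] + x[4:(n - 1)] - x[2:(n - 3)] - x[1:(n - 4)]) /
      (6 * dts)
    v[1:2] <- v[3]; v[(n - 1):n] <- v[n - 2]
    v
  }
  vx <- moving_average(sym_diff(gaze$x), cfg$velocity_window)
  vy <- moving_average(sym_diff(gaze$y), cfg$velocity_window)
  data.frame(t_ms = gaze$t_ms, vx = vx, vy = vy)
}

#' Detect saccades with a median-based elliptic velocity threshold
#'
#' Component spreads are estimated as
#' `sigma = sqrt(median(v^2) - median(v)^2)`; samples with
#' `(vx / (lambda sigma_x))^2 + (vy / (lambda sigma_y))^2 > 1` for at least
#' `min_duration_ms` form candidate events, events separated by less than
#' `min_separation_ms` are merged, and event boundaries are then extended
#' outward while the elliptic velocity statistic keeps decreasing, so that
#' onset/offset sit at the foot of the velocity peak rather than at the
#' threshold crossing.
#'
#' @param gaze Data frame `t_ms`, `x`, `y`.
#' @param cfg A [detection_config()].
#' @return Data frame of events: `onset_t`, `offset_t` (ms), `start_x`,
#'   `start_y`, `end_x`, `end_y`, `amplitude_dva`, `duration_ms`,
#'   `peak_vel_dva_s`.  Zero rows when nothing crosses the threshold.
#' @export
detect_saccades <- function(gaze, cfg = detection_config()) {
  vel <- compute_velocity(gaze, cfg)
  ok <- !is.na(vel$vx) & !is.na(vel$vy)
  if (!any(ok)) stop("all velocity samples are missing")
  sig <- function(v) {
    s2 <- stats::median(v^2, na.rm = TRUE) -
      stats::median(v, na.rm = TRUE)^2
    sqrt(max(s2, 0))
  }
  sx <- max(sig(vel$vx), 1e-8)
  sy <- max(sig(vel$vy), 1e-8)
  r <- sqrt((vel$vx / (cfg$lambda * sx))^2 + (vel$vy / (cfg$lambda * sy))^2)
  above <- !is.na(r) & r > 1

  dt <- gaze$t_ms[2] - gaze$t_ms[1]
  min_len <- max(2, ceiling(cfg$min_duration_ms / dt))
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  keep <- runs$values & runs$lengths >= min_len
  if (!any(keep)) return(empty_events())
  ev <- data.frame(i0 = starts[keep], i1 = ends[keep])

  # merge events closer than min_separation
  if (nrow(ev) > 1) {
    merged <- ev[1, , drop = FALSE]
    for (j in 2:nrow(ev)) {
      gap <- (ev$i0[j] - merged$i1[nrow(merged)] - 1) * dt
      if (gap < cfg$min_separation_ms)
        merged$i1[nrow(merged)] <- ev$i1[j]
      else merged <- rbind(merged, ev[j, ])
    }
    ev <- merged
  }

  # extend boundaries down the flanks of the velocity peak
  n <- nrow(gaze)
  for (j in seq_len(nrow(ev))) {
    i <- ev$i0[j]
    while (i > 1 && !is.na(r[i - 1]) && r[i - 1] < r[i]) i <- i - 1
    ev$i0[j] <- i
    i <- ev$i1[j]
    while (i < n && !is.na(r[i + 1]) && r[i + 1] < r[i]) i <- i + 1
    ev$i1[j] <- i
  }
  # extensions may have produced overlaps
  if (nrow(ev) > 1) {
    merged <- ev[1, , drop = FALSE]
    for (j in 2:nrow(ev)) {
      if (ev$i0[j] <= merged$i1[nrow(merged)] + 1)
        merged$i1[nrow(merged)] <- max(merged$i1[nrow(merged)], ev$i1[j])
      else merged <- rbind(merged, ev[j, ])
    }
    ev <- merged
  }

  speed <- sqrt(vel$vx^2 + vel$vy^2)
  data.frame(
    onset_t = gaze$t_ms[ev$i0],
    offset_t = gaze$t_ms[ev$i1],
    start_x = gaze$x[ev$i0], start_y = gaze$y[ev$i0],
    end_x = gaze$x[ev$i1], end_y = gaze$y[ev$i1],
    amplitude_dva = sqrt((gaze$x[ev$i1] - gaze$x[ev$i0])^2 +
                           (gaze$y[ev$i1] - gaze$y[ev$i0])^2),
    duration_ms = gaze$t_ms[ev$i1] - gaze$t_ms[ev$i0],
    peak_vel_dva_s = vapply(seq_len(nrow(ev)), function(j)
      max(speed[ev$i0[j]:ev$i1[j]], na.rm = TRUE), numeric(1))
  )
}

empty_events <- function() {
  data.frame(onset_t = numeric(0), offset_t = numeric(0),
             start_x = numeric(0), start_y = numeric(0),
             end_x = numeric(0), end_y = numeric(0),
             amplitude_dva = numeric(0), duration_ms = numeric(0),
             peak_vel_dva_s = numeric(0))
}

#' First interceptive saccade
#'
#' The first detected saccade with onset after target onset; its latency is
#' onset time minus target onset time.
#'
#' @param events Event table from [detect_saccades()].
#' @param target_onset_t Target onset time, ms.
#' @return One-row event with an added `latency_ms` column.
#' @export
first_interceptive_saccade <- function(events, target_onset_t = 0) {
  post <- events[events$onset_t > target_onset_t, , drop = FALSE]
  if (nrow(post) == 0)
    stop("no-saccade-trial: no saccade after target onset")
  ev <- post[1, , drop = FALSE]
  ev$latency_ms <- ev$onset_t - target_onset_t
  ev
}

#' Flag missing-data and pre-onset-movement violations
#'
#' A trial is invalid when gaze samples are missing in runs of 10 ms or more
#' (blinks), or when the eye moved before the target appeared: any detected
#' event starting in the 200 ms before target onset, or any pre-onset
#' excursion larger than 1 dva from the median fixation position.
#'
#' @param gaze Data frame `t_ms`, `x`, `y`.
#' @param events Event table from [detect_saccades()].
#' @param target_onset_t Target onset time, ms.
#' @return `TRUE` when the trial violates gaze-quality rules.
#' @export
preonset_violation <- function(gaze, events, target_onset_t = 0) {
  dt <- gaze$t_ms[2] - gaze$t_ms[1]
  miss <- is.na(gaze$x) | is.na(gaze$y)
  if (any(miss)) {
    runs <- rle(miss)
    if (any(runs$values & runs$lengths * dt >= 10)) return(TRUE)
  }
  pre <- gaze$t_ms >= target_onset_t - 200 & gaze$t_ms < target_onset_t
  if (any(events$onset_t >= target_onset_t - 200 &
            events$onset_t < target_onset_t)) return(TRUE)
  fx <- stats::median(gaze$x[pre], na.rm = TRUE)
  fy <- stats::median(gaze$y[pre], na.rm = TRUE)
  exc <- sqrt((gaze$x[pre] - fx)^2 + (gaze$y[pre] - fy)^2)
  any(exc > 1, na.rm = TRUE)
}

#' Sequential trial exclusions
#'
#' Applies the inclusion rules in order, each stage operating on the
#' survivors of the previous one: (1) missing gaze / blink / pre-onset
#' movement, (2) saccade latency outside [100, 600] ms, (3) amplitude outside
#' [3, 20] dva, (4) saccade duration above 100 ms, (5) pursuit speed above
#' 60 dva/s.
#'
#' @param trials Data frame with columns `trial_id`, `bad_gaze` (logical),
#'   `latency_ms`, `amplitude_dva`, `duration_ms`, `pursuit_speed_dva_s`
#'   (NA allowed at stage 5).
#' @return List with `kept` (surviving rows of `trials`), `report` (per-trial
#'   `trial_id`, `kept`, `reason`), and `counts` (per-stage exclusions with
#'   percentages of the survivors entering each stage).
#' @export
apply_exclusions <- function(trials) {
  reason <- rep(NA_character_, nrow(trials))
  alive <- rep(TRUE, nrow(trials))
  stages <- list(
    bad_gaze = function(d) d$bad_gaze | is.na(d$latency_ms),
    latency = function(d) d$latency_ms < 100 | d$latency_ms > 600,
    amplitude = function(d) d$amplitude_dva < 3 | d$amplitude_dva > 20,
    duration = function(d) d$duration_ms > 100,
    pursuit_speed = function(d) !is.na(d$pursuit_speed_dva_s) &
      d$pursuit_speed_dva_s > 60
  )
  counts <- data.frame(stage = names(stages), n_in = NA_integer_,
                       n_excluded = NA_integer_, pct = NA_real_)
  for (s in seq_along(stages)) {
    n_in <- sum(alive)
    viol <- alive & stages[[s]](trials)
    viol[is.na(viol)] <- FALSE
    reason[viol] <- names(stages)[s]
    alive <- alive & !viol
    counts$n_in[s] <- n_in
    counts$n_excluded[s] <- sum(viol)
    counts$pct[s] <- if (n_in > 0) 100 * sum(viol) / n_in else 0
  }
  list(kept = trials[alive, , drop = FALSE],
       report = data.frame(trial_id = trials$trial_id,
                           kept = as.integer(alive), reason = reason),
       counts = counts)
}
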