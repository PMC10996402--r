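# Synthetic experiment generator: trial geometry, gaze traces and perceptual
# reports with known ground-truth direction biases, emulating an interceptive
# saccade task with radially moving double-drift and control targets.
#
# Coordinates: origin at screen center (= fixation), +x right, +y up, units
# are degrees of visual angle (dva); time in ms, target onset at t = 0.

#' Simulation configuration
#'
#' Collects every generative parameter of the synthetic experiment.  Defaults
#' reproduce the main-experiment conditions: envelope speed 12 dva/s reaching
#' 8 dva eccentricity at the expected saccade landing, internal drift
#' ~8 dva/s, saccade latencies ~N(230, 40^2) ms truncated to [100, 600] ms,
#' main-sequence durations 23.6 + 2.94 A ms, open-loop pursuit at gain 0.66,
#' and true direction biases toward the internal drift of 24.6 deg
#' (perception), 25.3 deg (pursuit) and 11.0 deg (saccade).
#'
#' @param n_participants,n_trials Cohort size and trials per participant.
#' @param envelope_speed Envelope (external) speed, dva/s.
#' @param internal_speed Internal drift speed, dva/s (5/10/15 in the
#'   speed-manipulation variant).
#' @param beta_perc,beta_purs,beta_sacc True direction biases (degrees,
#'   toward the internal drift) of the perceptual report, the post-saccadic
#'   pursuit, and the saccade landing.
#' @param report_kappa Von Mises concentration of perceptual report noise
#'   (33 gives an angular SD of about 10 degrees).
#' @param latency_mean,latency_sd Saccade latency distribution (ms), truncated
#'   to [100, 600].
#' @param landing_noise_sd Isotropic landing scatter, dva (per component).
#' @param pursuit_gain Open-loop pursuit speed / envelope speed.
#' @param pursuit_dir_noise_sd Per-trial pursuit direction noise, degrees.
#' @param sample_rate Gaze sampling rate, Hz (>= 250).
#' @param gaze_noise_sd Per-sample isotropic gaze noise, dva.
#' @param saccade_bias_amp,saccade_bias_harmonic Systematic saccade-direction
#'   bias of `amp * sin(harmonic * saccade_direction)` degrees, a
#'   direction-dependent motor distortion that the calibration stage must
#'   learn.  It enters the landing as a rotation of the onset-to-landing
#'   displacement amplified by the saccade-amplitude / target-displacement
#'   leverage (see [simulate_gaze_trial()]).
#' @param expected_duration Expected saccade duration (ms) used for trial
#'   geometry; `NULL` applies the main-sequence formula to an 8-dva target
#'   with a 10% amplitude undershoot.
#' @param control_rotation Range (degrees) of the random rotation applied to
#'   control trajectories around the interception point.
#' @param pre_onset_ms Fixation recording before target onset, ms.
#' @param pursuit_tail_ms Recording after saccade landing, ms.
#' @param seed Master seed.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_participants = 8,
                       n_trials = 400,
                       envelope_speed = 12,
                       internal_speed = 8,
                       beta_perc = 24.6,
                       beta_purs = 25.3,
                       beta_sacc = 11.0,
                       report_kappa = 33,
                       latency_mean = 230,
                       latency_sd = 40,
                       landing_noise_sd = 0.75,
                       pursuit_gain = 0.66,
                       pursuit_dir_noise_sd = 10,
                       sample_rate = 1000,
                       gaze_noise_sd = 0.02,
                       saccade_bias_amp = 10,
                       saccade_bias_harmonic = 2,
                       expected_duration = NULL,
                       control_rotation = c(15, 35),
                       pre_onset_ms = 400,
                       pursuit_tail_ms = 250,
                       seed = 1) {
  stopifnot(envelope_speed > 0, internal_speed > 0,
            pursuit_gain > 0, pursuit_gain <= 1.5,
            sample_rate >= 250)
  structure(as.list(environment()), class = "sim_config")
}

#' Main-sequence saccade duration
#'
#' Duration in ms as a linear function of amplitude: `23.6 + 2.94 * A`.
#'
#' @param amplitude Saccade amplitude, dva (>= 0).
#' @return Duration in ms.
#' @export
saccade_duration <- function(amplitude) {
  if (any(amplitude < 0)) stop("amplitude must be non-negative")
  23.6 + 2.94 * amplitude
}

# Truncated normal draw via inverse-CDF (exact, vectorized).
rtruncnorm <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

#' Von Mises random angles
#'
#' Best-Fisher rejection sampler.
#'
#' @param n Number of draws.
#' @param mu Mean direction, degrees.
#' @param kappa Concentration (> 0).
#' @return Angles in degrees, wrapped to (-180, 180].
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  stopifnot(kappa > 0, n >= 0)
  if (!is.finite(kappa)) return(rep(wrap_angle(mu), n))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      u1 <- stats::runif(1); u2 <- stats::runif(1); u3 <- stats::runif(1)
      z <- cos(pi * u1)
      f <- (1 + r * z) / (r + z)
      cc <- kappa * (r - f)
      if (cc * (2 - cc) - u2 > 0 || log(cc / u2) + 1 - cc >= 0) {
        out[i] <- sign(u3 - 0.5) * acos(pmin(1, pmax(-1, f)))
        break
      }
    }
  }
  wrap_angle(mu + rad2deg(out))
}

unit_vec <- function(angle_deg) {
  th <- deg2rad(angle_deg)
  c(cos(th), sin(th))
}

rot2 <- function(v, angle_deg) {
  th <- deg2rad(angle_deg)
  c(cos(th) * v[1] - sin(th) * v[2],
    sin(th) * v[1] + cos(th) * v[2])
}

expected_saccade_duration <- function(config) {
  if (!is.null(config$expected_duration)) config$expected_duration
  else saccade_duration(0.9 * 8)   # 10% undershoot on the 8-dva target
}

#' Draw the geometry of one trial
#'
#' A random polar angle is drawn uniformly and the onset radius adjusted so
#' that the target, moving radially inward or outward (equiprobable) at the
#' envelope speed, reaches 8 dva of eccentricity at the expected saccade
#' landing time (expected latency plus expected duration).
#'
#' @param config A [sim_config()].
#' @param expected_latency Expected saccade latency in ms; in a session this
#'   is the mean of the previous 20 trials' latencies (200 ms before 20 trials
#'   have been collected).
#' @param condition `"dd"` (double drift) or `"control"`.
#' @param motion `"random"` (inward/outward equiprobable, the experimental
#'   condition) or a fixed motion direction.
#' @return A list (`trial_ground_truth`) with the physical direction,
#'   motion direction, onset position/eccentricity, expected interception
#'   point at 8 dva, internal-drift sign, and expected timing.  Uses the
#'   current RNG stream.
#' @export
make_trial_geometry <- function(config, expected_latency = 200,
                                condition = c("dd", "control"),
                                motion = c("random", "inward", "outward")) {
  condition <- match.arg(condition)
  motion <- match.arg(motion)
  if (expected_latency <= 0) stop("expected_latency must be positive")
  dur <- expected_saccade_duration(config)
  t_land <- (expected_latency + dur) / 1000           # s
  travel <- config$envelope_speed * t_land            # dva
  phi <- stats::runif(1, 0, 360)                      # polar angle of onset
  inward <- switch(motion, random = stats::runif(1) < 0.5,
                   inward = TRUE, outward = FALSE)
  if (inward) {
    onset_ecc <- 8 + travel
    phys_dir <- wrap_angle(phi + 180)
  } else {
    onset_ecc <- 8 - travel
    if (onset_ecc <= 0)
      stop("infeasible-geometry: outward onset eccentricity <= 0")
    phys_dir <- wrap_angle(phi)
  }
  onset_pos <- onset_ecc * unit_vec(phi)
  internal_sign <- if (condition == "dd") {
    if (stats::runif(1) < 0.5) 1L else -1L
  } else 0L
  structure(list(
    condition = condition,
    motion_dir = if (inward) "inward" else "outward",
    phys_dir = phys_dir,
    onset_pos = onset_pos,
    onset_ecc = onset_ecc,
    intercept_pos = 8 * unit_vec(phi),
    internal_sign = internal_sign,
    expected_latency = expected_latency,
    expected_duration = dur,
    control_rotation = 0
  ), class = "trial_ground_truth")
}

#' Rotate a control trajectory around the interception point
#'
#' Control trajectories are rotated around the expected interception point at
#' 8 dva of eccentricity by a random angle of magnitude uniform in the
#' configured range (default 15-35 degrees), added or subtracted with equal
#' probability, so that control targets are not exactly radial.
#'
#' @param truth A `trial_ground_truth` with `condition == "control"`.
#' @param config A [sim_config()].
#' @return The updated ground truth (direction and onset position rotated;
#'   the interception point is a fixed point of the rotation).
#' @export
rotate_control_trajectory <- function(truth, config) {
  if (truth$condition != "control")
    stop("rotate_control_trajectory applies to control trials only")
  lim <- config$control_rotation
  delta <- stats::runif(1, lim[1], lim[2]) *
    (if (stats::runif(1) < 0.5) 1 else -1)
  p <- truth$intercept_pos
  truth$onset_pos <- p + rot2(truth$onset_pos - p, delta)
  truth$phys_dir <- wrap_angle(truth$phys_dir + delta)
  truth$onset_ecc <- sqrt(sum(truth$onset_pos^2))
  truth$control_rotation <- delta
  truth
}

#' Simulate the gaze trace and responses of one trial
#'
#' Produces a uniformly sampled gaze trace: fixation jitter before the
#' saccade, a saccade with a raised-cosine velocity profile whose landing is
#' the target's position at landing time displaced along
#' `physical + internal_sign * beta_sacc`, distorted by the leveraged
#' systematic saccade-direction bias and jittered by landing noise; then
#' post-saccadic pursuit at `pursuit_gain * envelope_speed` along
#' `physical + internal_sign * beta_purs` plus per-trial direction noise.
#' Double-drift trials also get a perceptual report
#' `physical + internal_sign * beta_perc` plus von Mises noise.
#'
#' @param config A [sim_config()].
#' @param truth A `trial_ground_truth` from [make_trial_geometry()] (rotated
#'   for control trials).
#' @return List with `gaze` (data.frame `t_ms, x, y`), `trial` (stimulus
#'   record), and `truth` (per-trial ground truth including drawn latency,
#'   duration and landing).  Uses the current RNG stream.
#' @export
simulate_gaze_trial <- function(config, truth) {
  v <- config$envelope_speed
  dt <- 1000 / config$sample_rate                     # ms per sample
  latency <- rtruncnorm(1, config$latency_mean, config$latency_sd, 100, 600)

  # Landing point: fixed-point iteration because the main-sequence duration
  # depends on the saccade amplitude, which depends on the landing.
  sacc_target_dir <- wrap_angle(truth$phys_dir +
                                  truth$internal_sign * config$beta_sacc)
  dur <- saccade_duration(0.9 * 8)
  repeat {   # contraction with factor ~0.04, converges in a few steps
    landing_plan <- truth$onset_pos +
      v * (latency + dur) / 1000 * unit_vec(sacc_target_dir)
    dur_new <- saccade_duration(sqrt(sum(landing_plan^2)))
    if (abs(dur_new - dur) < 1e-10) break
    dur <- dur_new
  }
  # Direction-dependent saccade bias: landing errors proportional to saccade
  # amplitude act on the much shorter target-displacement (SVC) baseline, so
  # a motor bias of b degrees at saccade direction theta corrupts the SVC
  # direction by roughly b * amplitude / displacement.  The distortion is
  # injected as a rotation of the onset->landing displacement about the
  # target onset by that leveraged angle, which is exactly mean-zero over
  # the trial geometry and so leaves the configured beta_sacc identifiable.
  sacc_dir_plan <- rad2deg(atan2(landing_plan[2], landing_plan[1]))
  b <- config$saccade_bias_amp *
    sin(config$saccade_bias_harmonic * deg2rad(sacc_dir_plan))
  disp <- landing_plan - truth$onset_pos
  leverage <- sqrt(sum(landing_plan^2)) / sqrt(sum(disp^2))
  landing <- truth$onset_pos + rot2(disp, b * leverage) +
    stats::rnorm(2, 0, config$landing_noise_sd)

  t <- seq(-config$pre_onset_ms,
           latency + dur + config$pursuit_tail_ms, by = dt)
  n <- length(t)
  x <- numeric(n); y <- numeric(n)

  sacc <- t >= latency & t <= latency + dur
  u <- (t[sacc] - latency) / dur
  s <- u - sin(2 * pi * u) / (2 * pi)                 # raised-cosine profile
  x[sacc] <- landing[1] * s
  y[sacc] <- landing[2] * s

  purs <- t > latency + dur
  purs_dir <- wrap_angle(truth$phys_dir +
                           truth$internal_sign * config$beta_purs +
                           stats::rnorm(1, 0, config$pursuit_dir_noise_sd))
  pv <- config$pursuit_gain * v / 1000 * unit_vec(purs_dir)  # dva per ms
  x[purs] <- landing[1] + pv[1] * (t[purs] - latency - dur)
  y[purs] <- landing[2] + pv[2] * (t[purs] - latency - dur)

  if (config$gaze_noise_sd > 0) {
    x <- x + stats::rnorm(n, 0, config$gaze_noise_sd)
    y <- y + stats::rnorm(n, 0, config$gaze_noise_sd)
  }

  report <- NA_real_
  if (truth$condition == "dd") {
    mu <- wrap_angle(truth$phys_dir + truth$internal_sign * config$beta_perc)
    report <- rvonmises(1, mu, config$report_kappa)
  }

  truth$latency <- latency
  truth$duration <- dur
  truth$landing_pos <- landing
  truth$pursuit_dir_true <- purs_dir
  truth$true_biases <- c(perc = config$beta_perc, purs = config$beta_purs,
                         sacc = config$beta_sacc)

  trial <- list(condition = truth$condition, motion_dir = truth$motion_dir,
                onset_x_dva = truth$onset_pos[1],
                onset_y_dva = truth$onset_pos[2],
                onset_t_ms = 0,
                phys_dir_deg = truth$phys_dir,
                internal_sign = truth$internal_sign,
                internal_speed_dva_s = if (truth$condition == "dd")
                  config$internal_speed else 0,
                envelope_speed_dva_s = v,
                report_dir_deg = report)

  list(gaze = data.frame(t_ms = t, x = x, y = y),
       trial = trial, truth = truth)
}

#' Simulate a full cohort
#'
#' Simulates `n_participants x n_trials` trials (half double-drift, half
#' control, randomly interleaved within participant).  The expected latency
#' used for trial geometry is the running mean of the previous 20 drawn
#' latencies (200 ms until 20 trials have accumulated), as in the online
#' procedure it emulates.
#'
#' @param config A [sim_config()]; `config$seed` fixes the whole dataset.
#' @return List of data.frames `trials`, `gaze` (long, keyed by `trial_id`),
#'   and `truth`.
#' @export
simulate_experiment <- function(config = sim_config()) {
  set.seed(config$seed)
  trials <- vector("list", config$n_participants * config$n_trials)
  truths <- vector("list", length(trials))
  gazes  <- vector("list", length(trials))
  k <- 0
  for (p in seq_len(config$n_participants)) {
    half <- config$n_trials / 2
    conds <- sample(rep(c("dd", "control"),
                        c(ceiling(half), config$n_trials - ceiling(half))))
    lat_hist <- numeric(0)
    for (i in seq_len(config$n_trials)) {
      k <- k + 1
      exp_lat <- if (length(lat_hist) < 20) 200 else
        mean(utils::tail(lat_hist, 20))
      truth <- make_trial_geometry(config, exp_lat, conds[i])
      if (truth$condition == "control")
        truth <- rotate_control_trajectory(truth, config)
      sim <- simulate_gaze_trial(config, truth)
      lat_hist <- c(lat_hist, sim$truth$latency)
      id <- sprintf("p%02d_t%04d", p, i)
      trials[[k]] <- data.frame(trial_id = id, participant = p,
                                as.data.frame(sim$trial))
      truths[[k]] <- data.frame(
        trial_id = id, participant = p,
        beta_perc = config$beta_perc, beta_purs = config$beta_purs,
        beta_sacc = config$beta_sacc, pursuit_gain = config$pursuit_gain,
        latency_ms = sim$truth$latency, duration_ms = sim$truth$duration,
        landing_x = sim$truth$landing_pos[1],
        landing_y = sim$truth$landing_pos[2],
        pursuit_dir_deg = sim$truth$pursuit_dir_true,
        control_rotation_deg = sim$truth$control_rotation)
      g <- sim$gaze
      g$trial_id <- id
      gazes[[k]] <- g
    }
  }
  list(trials = do.call(rbind, trials),
       gaze = do.call(rbind, gazes)[, c("trial_id", "t_ms", "x", "y")],
       truth = do.call(rbind, truths))
}

#' Write a simulated dataset to disk
#'
#' Writes `trials.csv`, `gaze.csv` and `truth.csv` (RFC-4180, UTF-8, dot
#' decimal) to `dir`.  Deterministic under `config$seed`.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the list from [simulate_experiment()].
#' @export
generate_dataset <- function(config = sim_config(), dir = ".") {
  ds <- simulate_experiment(config)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(ds$trials, file.path(dir, "trials.csv"), row.names = FALSE)
  utils::write.csv(ds$gaze, file.path(dir, "gaze.csv"), row.names = FALSE)
  utils::write.csv(ds$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(ds)
}
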