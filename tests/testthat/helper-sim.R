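# Shared fixtures built in code.

# Generator with the response noise sources and the systematic motor
# distortion switched off: recovered biases must then equal the configured
# betas up to the sampling-grid discretization of event timing.  Sensor
# (gaze) noise is kept at its default so the median-based velocity threshold
# of the saccade detector remains well defined.
zero_noise_config <- function(...) {
  sim_config(landing_noise_sd = 0, pursuit_dir_noise_sd = 0,
             saccade_bias_amp = 0, report_kappa = Inf, ...)
}

# Synthetic feature tables for the calibration stage (no gaze traces):
# control trials carry the +/-U(15,35) trajectory rotation, double-drift
# trials the injected saccadic bias; the SVC direction is corrupted by a
# leveraged sinusoidal distortion of the saccade direction plus angular
# noise.
make_calib_features <- function(n, beta = 0, internal_sign = NULL,
                                distortion_amp = 10, leverage = 2.4,
                                noise_sd = 13, control = TRUE) {
  phi <- runif(n, -180, 180)                 # saccade (radial) direction
  if (control) {
    delta <- runif(n, 15, 35) * sample(c(-1, 1), n, replace = TRUE)
    s <- rep(0L, n)
  } else {
    delta <- 0
    if (is.null(internal_sign)) s <- sample(c(-1L, 1L), n, replace = TRUE)
    else s <- rep(as.integer(internal_sign), n)
  }
  theta_true <- wrap_angle(phi + delta)
  sacc_dir <- wrap_angle(phi + 0.41 * s * beta)
  svc <- wrap_angle(theta_true + s * beta +
                      distortion_amp * leverage * sin(2 * deg2rad(sacc_dir)) +
                      rnorm(n, 0, noise_sd))
  data.frame(phys_dir_deg = theta_true, svc_angle_deg = svc,
             sacc_dir_deg = sacc_dir,
             latency_ms = runif(n, 150, 350),
             amplitude_dva = runif(n, 6, 10),
             internal_sign = s)
}

deg2rad <- driftgaze:::deg2rad
rad2deg <- driftgaze:::rad2deg
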