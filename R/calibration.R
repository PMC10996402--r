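# Saccadic velocity compensation (SVC) and its calibration: a family of 32
# circular-circular regression models fit on control trials (sine and cosine
# of the target direction as dependent variables), selected by leave-one-out
# cross-validation, used to read out the direction estimate of the saccadic
# system from saccade landings.  Also the saccadic speed estimate and the
# two-segment extrapolation-interval solver.

#' Saccadic velocity compensation vector
#'
#' The target velocity vector for which the observed saccade would have
#' landed with zero error: the difference between the saccade end point and
#' the target's starting position, divided by the interval from target onset
#' to saccade offset.
#'
#' @param onset_pos Target onset position `c(x, y)`, dva.
#' @param end_pos Saccade landing position `c(x, y)`, dva.
#' @param onset_t Target onset time, ms.
#' @param offset_t Saccade offset time, ms.
#' @return List of class `"svc"`: `vx`, `vy` (dva/s), `angle` (deg),
#'   `magnitude` (dva/s).
#' @export
compute_svc <- function(onset_pos, end_pos, onset_t, offset_t) {
  interval <- (offset_t - onset_t) / 1000
  if (interval <= 0) stop("non-positive onset-to-landing interval")
  vx <- (end_pos[1] - onset_pos[1]) / interval
  vy <- (end_pos[2] - onset_pos[2]) / interval
  structure(list(vx = vx, vy = vy,
                 angle = wrap_angle(rad2deg(atan2(vy, vx))),
                 magnitude = sqrt(vx^2 + vy^2)),
            class = "svc")
}

#' Saccadic estimate of target speed
#'
#' The absolute distance between the target onset position and the saccade
#' landing position divided by the onset-to-landing interval; identical to
#' the SVC magnitude.
#'
#' @inheritParams compute_svc
#' @return Speed in dva/s.
#' @export
saccadic_speed_estimate <- function(onset_pos, end_pos, onset_t, offset_t) {
  compute_svc(onset_pos, end_pos, onset_t, offset_t)$magnitude
}

#' Enumerate the 32-model calibration family
#'
#' All models contain a trigonometric polynomial of the SVC direction angle
#' (degree 1 or 2) and of the saccade direction angle (degree 1 or 2, with or
#' without interaction with the SVC terms), with or without interactions
#' between the SVC terms and the (z-scored) saccadic latency and amplitude:
#' 2 x 4 x 2 x 2 = 32 specifications.
#'
#' @return Data frame of 32 rows: `svc_degree`, `sacdir_degree`,
#'   `sacdir_interaction`, `latency_interaction`, `amplitude_interaction`.
#' @export
enumerate_model_specs <- function() {
  g <- expand.grid(svc_degree = 1:2, sacdir_degree = 1:2,
                   sacdir_interaction = c(FALSE, TRUE),
                   latency_interaction = c(FALSE, TRUE),
                   amplitude_interaction = c(FALSE, TRUE))
  g$spec_id <- seq_len(nrow(g))
  g
}

trig_block <- function(theta_deg, degree, prefix) {
  th <- deg2rad(theta_deg)
  out <- NULL
  for (k in seq_len(degree)) {
    blk <- cbind(cos(k * th), sin(k * th))
    colnames(blk) <- paste0(prefix, c("_cos", "_sin"), k)
    out <- cbind(out, blk)
  }
  out
}

#' Build the design matrix of a calibration model
#'
#' Trials must carry `svc_angle_deg`, `sacc_dir_deg`, `latency_ms`,
#' `amplitude_dva`.  Latency and amplitude are z-scored with the training
#' scaling (computed here when `scaling` is `NULL`).
#'
#' @param spec One row of [enumerate_model_specs()].
#' @param trials Data frame of trials.
#' @param scaling Optional list `lat_mean, lat_sd, amp_mean, amp_sd` from the
#'   training set.
#' @return Design matrix with attribute `"scaling"`.
#' @export
build_design <- function(spec, trials, scaling = NULL) {
  need <- c("svc_angle_deg", "sacc_dir_deg", "latency_ms", "amplitude_dva")
  if (!all(need %in% names(trials)))
    stop("missing covariates: ", paste(setdiff(need, names(trials)),
                                       collapse = ", "))
  if (is.null(scaling)) {
    scaling <- list(lat_mean = mean(trials$latency_ms),
                    lat_sd = max(stats::sd(trials$latency_ms), 1e-12),
                    amp_mean = mean(trials$amplitude_dva),
                    amp_sd = max(stats::sd(trials$amplitude_dva), 1e-12))
  }
  svc <- trig_block(trials$svc_angle_deg, spec$svc_degree, "svc")
  sac <- trig_block(trials$sacc_dir_deg, spec$sacdir_degree, "sac")
  X <- cbind(intercept = rep(1, nrow(trials)), svc, sac)
  if (spec$sacdir_interaction) {
    inter <- NULL
    for (i in seq_len(ncol(svc))) for (j in seq_len(ncol(sac))) {
      cl <- svc[, i] * sac[, j]
      inter <- cbind(inter, cl)
      colnames(inter)[ncol(inter)] <- paste0(colnames(svc)[i], ":",
                                             colnames(sac)[j])
    }
    X <- cbind(X, inter)
  }
  if (spec$latency_interaction) {
    zl <- (trials$latency_ms - scaling$lat_mean) / scaling$lat_sd
    blk <- svc * zl
    colnames(blk) <- paste0(colnames(svc), ":lat")
    X <- cbind(X, blk)
  }
  if (spec$amplitude_interaction) {
    za <- (trials$amplitude_dva - scaling$amp_mean) / scaling$amp_sd
    blk <- svc * za
    colnames(blk) <- paste0(colnames(svc), ":amp")
    X <- cbind(X, blk)
  }
  attr(X, "scaling") <- scaling
  X
}

#' Fit one calibration model
#'
#' Two least-squares regressions on the shared design, with the cosine and
#' sine of the true target direction (`phys_dir_deg`) as dependent variables;
#' the predicted direction is the `atan2` of the two linear predictors.  The
#' leave-one-out cross-validated error (mean absolute wrapped angular
#' difference between held-out predictions and true directions) is computed
#' exactly from the hat-matrix identity for linear smoothers.
#'
#' @param spec One row of [enumerate_model_specs()].
#' @param trials Training trials (control condition) carrying
#'   `phys_dir_deg` and the covariates of [build_design()].
#' @return Object of class `"calibration_model"`: `spec`, `coef` (matrix with
#'   columns `cos`, `sin`), `scaling`, `cv_error` (deg), `n_train`,
#'   `r2_cos`, `r2_sin`.
#' @export
fit_model <- function(spec, trials) {
  X <- build_design(spec, trials)
  if (nrow(X) <= ncol(X))
    stop("not enough training trials for this model")
  th <- deg2rad(trials$phys_dir_deg)
  Y <- cbind(cos = cos(th), sin = sin(th))
  qx <- qr(X)
  if (qx$rank < ncol(X)) stop("rank-deficient design")
  coef <- qr.coef(qx, Y)
  fitted <- X %*% coef
  resid <- Y - fitted
  h <- rowSums(qr.Q(qx)^2)
  if (any(1 - h < 1e-10)) stop("rank-deficient design: leverage 1 fold")
  loo <- Y - resid / (1 - h)      # held-out linear predictors
  loo_angle <- rad2deg(atan2(loo[, 2], loo[, 1]))
  cv_error <- mean(abs(ang_diff(loo_angle, trials$phys_dir_deg)))
  r2 <- function(j) 1 - sum(resid[, j]^2) / sum((Y[, j] - mean(Y[, j]))^2)
  structure(list(spec = spec, coef = coef, scaling = attr(X, "scaling"),
                 cv_error = cv_error, n_train = nrow(X),
                 r2_cos = r2(1), r2_sin = r2(2)),
            class = "calibration_model")
}

#' Leave-one-out cross-validated angular error of one model
#'
#' @inheritParams fit_model
#' @return Mean absolute wrapped angular error (degrees) over the n
#'   leave-one-out folds.
#' @export
loo_cv <- function(spec, trials) fit_model(spec, trials)$cv_error

#' Select the best calibration model by LOO-CV
#'
#' Evaluates all specifications (models whose design cannot be fit on the
#' training set are dropped) and returns the fitted model with the smallest
#' cross-validated error; ties are broken by fewer design columns, then by
#' enumeration order.
#'
#' @param trials Training (control) trials.
#' @param specs Model family, default [enumerate_model_specs()].
#' @return The selected `"calibration_model"`, with the per-spec CV table in
#'   `$cv_table`.
#' @export
select_model <- function(trials, specs = enumerate_model_specs()) {
  fits <- vector("list", nrow(specs))
  cv <- rep(Inf, nrow(specs))
  ncols <- rep(NA_integer_, nrow(specs))
  for (i in seq_len(nrow(specs))) {
    fit <- tryCatch(fit_model(specs[i, ], trials), error = function(e) NULL)
    if (!is.null(fit)) {
      fits[[i]] <- fit
      cv[i] <- fit$cv_error
      ncols[i] <- nrow(fit$coef)
    }
  }
  if (all(is.infinite(cv))) stop("no calibration model could be fit")
  ord <- order(cv, ncols, specs$spec_id)
  best <- fits[[ord[1]]]
  best$cv_table <- cbind(specs, cv_error = cv, n_columns = ncols)
  best
}

#' Predict the target direction from a fitted calibration model
#'
#' @param model A `"calibration_model"`.
#' @param trials Trials carrying the covariates used by the model's spec.
#' @return Predicted directions in degrees (`atan2` of the sine and cosine
#'   linear predictors).
#' @export
predict_target_direction <- function(model, trials) {
  X <- build_design(model$spec, trials, scaling = model$scaling)
  P <- X %*% model$coef
  wrap_angle(rad2deg(atan2(P[, 2], P[, 1])))
}

#' @export
print.calibration_model <- function(x, ...) {
  s <- x$spec
  cat(sprintf(paste0("Calibration model: SVC degree %d, saccade-direction ",
                     "degree %d%s%s%s\n"),
              s$svc_degree, s$sacdir_degree,
              if (s$sacdir_interaction) " (interaction)" else "",
              if (s$latency_interaction) " + latency" else "",
              if (s$amplitude_interaction) " + amplitude" else ""))
  cat(sprintf("  n = %d, LOO-CV error = %.2f deg, R2 = %.3f (cos) / %.3f (sin)\n",
              x$n_train, x$cv_error, x$r2_cos, x$r2_sin))
  invisible(x)
}

#' Extrapolation interval of the saccadic system
#'
#' Two-segment account of why the saccadic direction bias is smaller than
#' the pursuit bias: the saccade target is extrapolated along the physical
#' direction for `t_total - t_e` and along the (biased) early-pursuit
#' direction for `t_e`.  Solves, by bisection to 0.01 ms, for the
#' extrapolation interval `t_e` at which the angle of the summed displacement
#' equals the observed saccadic bias.
#'
#' @param bias_sacc Saccadic direction bias, degrees (`0 <= bias_sacc <=
#'   bias_purs`).
#' @param bias_purs Pursuit direction bias, degrees.
#' @param t_total Total onset-to-landing interval, ms.
#' @param speed Target speed, dva/s (cancels in the angle; kept for the
#'   record).
#' @return List of class `"extrapolation_estimate"`: `t_e`, `t_total`,
#'   `inputs`.
#' @export
estimate_extrapolation_interval <- function(bias_sacc, bias_purs, t_total,
                                            speed = 12) {
  if (t_total <= 0) stop("t_total must be positive")
  if (bias_sacc < 0 || bias_sacc > bias_purs)
    stop("bias_sacc must lie in [0, bias_purs]")
  ang <- function(te) {
    d <- speed * (t_total - te) / 1000 * unit_vec(0) +
      speed * te / 1000 * unit_vec(bias_purs)
    rad2deg(atan2(d[2], d[1]))
  }
  if (bias_sacc == 0) te <- 0
  else if (bias_sacc == bias_purs) te <- t_total
  else {
    lo <- 0; hi <- t_total
    if (ang(hi) < bias_sacc) stop("no root in [0, t_total]")
    while (hi - lo > 0.01) {
      mid <- (lo + hi) / 2
      if (ang(mid) < bias_sacc) lo <- mid else hi <- mid
    }
    te <- (lo + hi) / 2
  }
  structure(list(t_e = te, t_total = t_total,
                 inputs = c(bias_sacc = bias_sacc, bias_purs = bias_purs,
                            speed = speed)),
            class = "extrapolation_estimate")
}

#' @export
print.extrapolation_estimate <- function(x, ...) {
  cat(sprintf(paste0("Extrapolation interval: t_e = %.1f ms of %.0f ms total",
                     " (saccade bias %.2f deg, pursuit bias %.2f deg)\n"),
              x$t_e, x$t_total, x$inputs["bias_sacc"], x$inputs["bias_purs"]))
  invisible(x)
}
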