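test_that("SVC is displacement over onset-to-landing time", {
  svc <- compute_svc(c(0, 0), c(3, 0), 0, 250)
  expect_equal(c(svc$vx, svc$vy), c(12, 0))
  expect_equal(svc$angle, 0)
  expect_equal(svc$magnitude, 12)
  expect_error(compute_svc(c(0, 0), c(3, 0), 100, 100), "non-positive")
  expect_equal(saccadic_speed_estimate(c(0, 0), c(0, 3), 0, 250), 12)
  # speed estimate equals SVC magnitude on arbitrary trials
  set.seed(51)
  for (i in 1:10) {
    o <- rnorm(2); e <- rnorm(2); dt <- runif(1, 100, 400)
    expect_identical(saccadic_speed_estimate(o, e, 0, dt),
                     compute_svc(o, e, 0, dt)$magnitude)
  }
})

test_that("the model family enumerates 32 distinct specifications", {
  specs <- enumerate_model_specs()
  expect_equal(nrow(specs), 32)
  expect_equal(nrow(unique(specs[, 1:5])), 32)
  expect_setequal(unique(specs$svc_degree), 1:2)
  expect_setequal(unique(specs$sacdir_degree), 1:2)
})

test_that("design matrices have the expected column counts", {
  set.seed(52)
  d <- make_calib_features(40)
  specs <- enumerate_model_specs()
  pick <- function(sv, sa, si, li, ai) {
    specs[specs$svc_degree == sv & specs$sacdir_degree == sa &
            specs$sacdir_interaction == si & specs$latency_interaction == li &
            specs$amplitude_interaction == ai, ]
  }
  expect_equal(ncol(build_design(pick(1, 1, FALSE, FALSE, FALSE), d)), 5)
  expect_equal(ncol(build_design(pick(2, 2, TRUE, FALSE, FALSE), d)), 25)
  expect_equal(ncol(build_design(pick(2, 2, TRUE, TRUE, TRUE), d)),
               1 + 4 + 4 + 16 + 4 + 4)
  expect_error(build_design(pick(1, 1, FALSE, FALSE, FALSE), d[, 1:2]),
               "missing covariates")
})

test_that("an identity SVC-target relation is fit with zero error", {
  set.seed(53)
  d <- make_calib_features(60, distortion_amp = 0, noise_sd = 0)
  d$svc_angle_deg <- d$phys_dir_deg
  spec <- enumerate_model_specs()[1, ]
  fit <- fit_model(spec, d)
  expect_lt(fit$cv_error, 1e-8)
  expect_gte(fit$r2_cos, 0.999)
  expect_true(fit$r2_cos <= 1 && fit$r2_sin <= 1)
  pred <- predict_target_direction(fit, transform(d, svc_angle_deg = 40))
  expect_equal(pred, rep(40, 60), tolerance = 1e-6)
})

test_that("hat-matrix LOO equals brute-force refitting", {
  set.seed(54)
  d <- make_calib_features(60)
  for (i in c(1, 8, 23, 32)) {
    spec <- enumerate_model_specs()[i, ]
    got <- loo_cv(spec, d)
    # independent oracle: n explicit least-squares refits on the shared
    # design (covariates are z-scored once on the training set, so the
    # design rows are fixed across folds)
    full <- fit_model(spec, d)
    Xall <- build_design(spec, d, scaling = full$scaling)
    th <- d$phys_dir_deg * pi / 180
    Y <- cbind(cos(th), sin(th))
    errs <- vapply(seq_len(nrow(d)), function(k) {
      cf <- qr.coef(qr(Xall[-k, , drop = FALSE]), Y[-k, , drop = FALSE])
      p <- Xall[k, , drop = FALSE] %*% cf
      abs(ang_diff(atan2(p[2], p[1]) * 180 / pi, d$phys_dir_deg[k]))
    }, numeric(1))
    expect_equal(got, mean(errs), tolerance = 1e-10)
  }
})

test_that("pure-noise predictors give ~90 degrees of cross-validated error", {
  set.seed(55)
  d <- make_calib_features(2000, distortion_amp = 0, noise_sd = 0)
  d$svc_angle_deg <- runif(2000, -180, 180)   # unrelated to the target
  d$sacc_dir_deg <- runif(2000, -180, 180)
  spec <- enumerate_model_specs()[1, ]
  expect_equal(loo_cv(spec, d), 90, tolerance = 5)
})

test_that("model selection recovers the degree-2 saccade-direction distortion", {
  set.seed(56)
  wins <- 0
  for (r in 1:100) {
    d <- make_calib_features(100)
    best <- select_model(d)
    if (best$spec$sacdir_degree == 2) wins <- wins + 1
  }
  expect_gte(wins, 80)
})

test_that("without distortion the selected model is no better than the simplest", {
  set.seed(57)
  d <- make_calib_features(1500, distortion_amp = 0, noise_sd = 10)
  d$sacc_dir_deg <- runif(1500, -180, 180)   # uninformative saccade direction
  best <- select_model(d)
  simplest <- loo_cv(enumerate_model_specs()[1, ], d)
  expect_lte(best$cv_error, simplest)
  expect_gte(best$cv_error, simplest * 0.95)
  # selection is deterministic given the table
  best2 <- select_model(d)
  expect_identical(best$spec, best2$spec)
})

test_that("predictions are invariant to joint rescaling of the coefficients", {
  set.seed(58)
  d <- make_calib_features(80)
  fit <- fit_model(enumerate_model_specs()[8, ], d)
  p1 <- predict_target_direction(fit, d)
  fit$coef <- fit$coef * 3.7
  expect_equal(predict_target_direction(fit, d), p1, tolerance = 1e-9)
})

test_that("calibrated predictions recover an injected saccadic bias", {
  set.seed(59)
  biases <- replicate(20, {
    ctrl <- make_calib_features(200, noise_sd = 6)
    dd <- make_calib_features(200, beta = 11, control = FALSE, noise_sd = 6)
    best <- select_model(ctrl)
    pred <- predict_target_direction(best, dd)
    as.numeric(angular_mean(dd$internal_sign *
                              ang_diff(pred, dd$phys_dir_deg)))
  })
  expect_equal(mean(biases), 11, tolerance = 1)
})

test_that("calibration is equivariant under global rotation of the scene", {
  set.seed(60)
  ctrl <- make_calib_features(150)
  dd <- make_calib_features(150, beta = 11, control = FALSE)
  spec <- enumerate_model_specs()[24, ]
  bias_of <- function(rot) {
    rc <- ctrl; rd <- dd
    for (col in c("phys_dir_deg", "svc_angle_deg", "sacc_dir_deg")) {
      rc[[col]] <- wrap_angle(rc[[col]] + rot)
      rd[[col]] <- wrap_angle(rd[[col]] + rot)
    }
    fit <- fit_model(spec, rc)
    pred <- predict_target_direction(fit, rd)
    c(fit$cv_error,
      as.numeric(angular_mean(rd$internal_sign *
                                ang_diff(pred, rd$phys_dir_deg))))
  }
  b0 <- bias_of(0)
  for (rot in c(45, -160)) expect_equal(bias_of(rot), b0, tolerance = 1e-6)
})

test_that("the two-segment extrapolation interval matches its closed form", {
  expect_equal(estimate_extrapolation_interval(0, 25, 266)$t_e, 0)
  expect_equal(estimate_extrapolation_interval(25, 25, 266)$t_e, 266)
  est <- estimate_extrapolation_interval(10.98, 25.25, 266)
  # closed-form oracle: tan(bias_sacc) = s sin(b) / (1 - s + s cos(b))
  b <- 25.25 * pi / 180; th <- 10.98 * pi / 180
  s <- tan(th) / (sin(b) - tan(th) * cos(b) + tan(th))
  expect_equal(est$t_e, s * 266, tolerance = 0.02)
  expect_error(estimate_extrapolation_interval(30, 25, 266), "bias_sacc")
  expect_error(estimate_extrapolation_interval(10, 25, -5), "t_total")
  # monotone in the saccadic bias
  tes <- vapply(seq(1, 24, by = 1), function(bs)
    estimate_extrapolation_interval(bs, 25.25, 266)$t_e, numeric(1))
  expect_true(all(diff(tes) > 0))
})
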