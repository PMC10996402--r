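mk_trace <- function(n = 600, dt = 1, fun_x = function(t) 0 * t,
                     fun_y = function(t) 0 * t) {
  t <- seq(0, by = dt, length.out = n)
  data.frame(t_ms = t, x = fun_x(t), y = fun_y(t))
}

test_that("the FIR low-pass filter preserves DC and low frequencies, kills high", {
  g <- mk_trace(800, fun_x = function(t) rep(0.7, length(t)))
  f <- lowpass_filter(g)
  i <- 150:700
  expect_lt(max(abs(f$x[i] - 0.7)), 1e-6)

  g5 <- mk_trace(1200, fun_x = function(t) sin(2 * pi * 5 * t / 1000))
  f5 <- lowpass_filter(g5)
  i <- 200:1000
  expect_lt(abs(max(abs(f5$x[i])) - 1), 0.02)           # 5 Hz within 2%

  g100 <- mk_trace(1200, fun_x = function(t) sin(2 * pi * 100 * t / 1000))
  f100 <- lowpass_filter(g100)
  expect_lt(max(abs(f100$x[i])), 10^(-20 / 20))          # >= 20 dB down
  expect_error(lowpass_filter(mk_trace(50)), "shorter")
})

test_that("the post-saccadic window has inclusive bounds and guards its edges", {
  g <- mk_trace(500)
  sac <- data.frame(offset_t = 150)
  sl <- postsaccadic_window(g, sac)
  expect_equal(nrow(sl), 81)
  expect_equal(range(sl$t_ms), c(170, 250))
  expect_error(postsaccadic_window(mk_trace(201), sac), "short-trial")
  gf <- lowpass_filter(mk_trace(320))   # window reaches into NA tail
  expect_error(postsaccadic_window(gf, data.frame(offset_t = 200)),
               "short-trial")
})

test_that("pursuit direction and speed are exact on linear motion", {
  lin <- function(speed, ang) {
    mk_trace(81, fun_x = function(t) speed * cos(ang * pi / 180) * t / 1000,
             fun_y = function(t) speed * sin(ang * pi / 180) * t / 1000)
  }
  sl <- lin(8, 30)
  expect_equal(pursuit_direction(sl), 30, tolerance = 1e-9)
  expect_equal(pursuit_speed(sl), 8, tolerance = 1e-9)
  rev <- sl[nrow(sl):1, ]; rev$t_ms <- sl$t_ms
  expect_equal(pursuit_direction(rev), wrap_angle(210), tolerance = 1e-9)
  still <- mk_trace(81)
  expect_equal(pursuit_speed(still), 0)
  expect_error(pursuit_direction(still), "degenerate")
  expect_error(pursuit_direction(sl[1:5, ]))
})

test_that("pursuit direction is rotation equivariant", {
  set.seed(41)
  sl <- mk_trace(81, fun_x = function(t) 0.008 * t,
                 fun_y = function(t) 0.002 * t)
  sl$x <- sl$x + rnorm(81, 0, 0.01); sl$y <- sl$y + rnorm(81, 0, 0.01)
  d0 <- pursuit_direction(sl)
  for (phi in c(30, -120, 90)) {
    rot <- sl
    th <- phi * pi / 180
    rot$x <- cos(th) * sl$x - sin(th) * sl$y
    rot$y <- sin(th) * sl$x + cos(th) * sl$y
    expect_equal(pursuit_direction(rot), wrap_angle(d0 + phi),
                 tolerance = 1e-9)
  }
})

test_that("direction error under isotropic noise stays within 3 degrees", {
  set.seed(42)
  # noisy linear motion, processed as in the pipeline: low-pass filter on the
  # full trace, then the 81-sample open-loop window
  errs <- replicate(1000, {
    g <- mk_trace(500, fun_x = function(t) 8 * cos(0.7) * t / 1000,
                  fun_y = function(t) 8 * sin(0.7) * t / 1000)
    g$x <- g$x + rnorm(500, 0, 0.05)
    g$y <- g$y + rnorm(500, 0, 0.05)
    sl <- postsaccadic_window(lowpass_filter(g), data.frame(offset_t = 180))
    abs(ang_diff(pursuit_direction(sl), 0.7 * 180 / pi))
  })
  # sampling error of orthogonal regression at these numbers: ~1.9 deg SD
  expect_gte(mean(errs <= 3), 0.90)
  expect_gte(mean(errs <= 4), 0.95)
  expect_lte(median(errs), 1.5)
})

test_that("norm of mean velocity never exceeds mean speed", {
  set.seed(43)
  sl <- mk_trace(81, fun_x = function(t) 0.008 * t)
  sl$x <- sl$x + rnorm(81, 0, 0.05); sl$y <- rnorm(81, 0, 0.05)
  dts <- diff(sl$t_ms) / 1000
  mean_of_norms <- mean(sqrt((diff(sl$x) / dts)^2 + (diff(sl$y) / dts)^2))
  expect_lte(pursuit_speed(sl), mean_of_norms)
})

test_that("filtering a padded trace and slicing match the unpadded pipeline", {
  set.seed(44)
  x <- cumsum(rnorm(900, 0, 0.05))
  g <- data.frame(t_ms = 0:899, x = x, y = rev(x))
  pad <- data.frame(t_ms = -200:-1, x = rnorm(200, x[1], 0.01),
                    y = rnorm(200, x[900], 0.01))
  gp <- rbind(pad, g)
  f1 <- lowpass_filter(g)
  f2 <- lowpass_filter(gp)
  sac <- data.frame(offset_t = 400)
  s1 <- postsaccadic_window(f1, sac)
  s2 <- postsaccadic_window(f2, sac)
  expect_equal(s1$x, s2$x, tolerance = 1e-12)
  expect_equal(s1$y, s2$y, tolerance = 1e-12)
})

test_that("presaccadic pursuit is returned only above the baseline threshold", {
  set.seed(45)
  quiet <- function() {
    g <- mk_trace(700)
    g$t_ms <- g$t_ms - 350                 # target onset at 0, saccade at 250
    g$x <- rnorm(700, 0, 0.005); g$y <- rnorm(700, 0, 0.005)
    g
  }
  sac <- data.frame(onset_t = 250)
  g <- quiet()
  out <- presaccadic_pursuit(lowpass_filter(g), sac, 0)
  expect_false(out$above_threshold)
  expect_true(is.na(out$direction))

  # inject a 3 dva/s drift at 40 degrees starting 150 ms before saccade onset
  drifted <- function() {
    g <- quiet()
    on <- g$t_ms >= 100
    dt <- (g$t_ms[on] - 100) / 1000
    g$x[on] <- g$x[on] + 3 * cos(40 * pi / 180) * dt
    g$y[on] <- g$y[on] + 3 * sin(40 * pi / 180) * dt
    g
  }
  out2 <- presaccadic_pursuit(lowpass_filter(drifted()), sac, 0)
  expect_true(out2$above_threshold)
  expect_lt(abs(ang_diff(out2$direction, 40)), 5)

  # mechanism check: with drift injected on 12% of trials the detection
  # fraction tracks the injection rate
  hits <- replicate(200, {
    inject <- runif(1) < 0.12
    g <- if (inject) drifted() else quiet()
    presaccadic_pursuit(lowpass_filter(g), sac, 0)$above_threshold
  })
  expect_lt(abs(mean(hits) - 0.12), 0.08)
})
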