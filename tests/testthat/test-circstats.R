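test_that("wrap_angle returns the representative in (-180, 180]", {
  expect_equal(wrap_angle(190), -170)
  expect_equal(wrap_angle(-180), 180)
  expect_equal(wrap_angle(45), 45)
  expect_equal(wrap_angle(c(360, -360, 540)), c(0, 0, 180))
  expect_error(wrap_angle(NaN), "invalid-angle")
  expect_error(wrap_angle(Inf), "invalid-angle")
  set.seed(1)
  a <- runif(200, -1e4, 1e4)
  w <- wrap_angle(a)
  expect_true(all(w > -180 & w <= 180))
  expect_equal((a - w) %% 360, rep(0, 200), tolerance = 1e-9)
})

test_that("ang_diff is the wrapped signed difference", {
  expect_equal(ang_diff(350, 10), -20)
  expect_equal(ang_diff(10, 350), 20)
  expect_equal(ang_diff(123.4, 123.4), 0)
  expect_error(ang_diff(NA_real_, 0))
})

test_that("angular_mean matches atan2 of mean components and flags zero resultant", {
  expect_equal(as.numeric(angular_mean(c(10, 350))), 0)
  expect_equal(as.numeric(angular_mean(c(0, 90))), 45)
  expect_error(angular_mean(c(0, 180)), "undefined-mean")
  expect_error(angular_mean(numeric(0)))
  m <- angular_mean(c(40, 50))
  expect_equal(attr(m, "rbar"), cos(5 * pi / 180), tolerance = 1e-12)
})

test_that("circular statistics are rotation invariant / equivariant", {
  set.seed(42)
  for (i in 1:20) {
    a <- wrap_angle(rnorm(30, runif(1, -180, 180), 40))
    shift <- runif(1, -360, 360)
    m1 <- angular_mean(a)
    m2 <- angular_mean(wrap_angle(a + shift))
    expect_equal(as.numeric(m2), wrap_angle(as.numeric(m1) + shift),
                 tolerance = 1e-9)
    expect_equal(attr(m2, "rbar"), attr(m1, "rbar"), tolerance = 1e-12)
    expect_equal(rayleigh_test(wrap_angle(a + shift))$p, rayleigh_test(a)$p,
                 tolerance = 1e-12)
    b <- wrap_angle(a + rnorm(30, 0, 25))
    expect_equal(circ_corr(wrap_angle(a + shift), b)$r, circ_corr(a, b)$r,
                 tolerance = 1e-9)
  }
})

test_that("rayleigh_test follows the finite-n formula", {
  r <- rayleigh_test(c(0, 90, 180, 270))
  expect_equal(r$rbar, 0, tolerance = 1e-12)
  expect_equal(r$p, 1, tolerance = 1e-9)
  r2 <- rayleigh_test(rep(33, 100))
  expect_equal(r2$rbar, 1, tolerance = 1e-12)
  expect_lt(r2$p, 1e-10)
  expect_equal(r2$p, exp(sqrt(1 + 400) - 201), tolerance = 1e-9)
  expect_equal(r2$z, 100)
  expect_error(rayleigh_test(5))
})

test_that("rayleigh_test type-I error is calibrated at alpha = 0.05", {
  set.seed(7)
  for (n in c(8, 50, 200)) {
    reps <- 3000
    th <- matrix(runif(reps * n, 0, 2 * pi), reps)
    rbar <- sqrt(rowMeans(sin(th))^2 + rowMeans(cos(th))^2)
    R <- n * rbar
    p <- exp(sqrt(1 + 4 * n + 4 * (n^2 - R^2)) - (1 + 2 * n))
    rate <- mean(p < 0.05)
    ci <- 2.576 * sqrt(0.05 * 0.95 / reps)
    expect_true(abs(rate - 0.05) < ci + 0.005,
                label = sprintf("n=%d rate=%.4f", n, rate))
    # the vectorized null above must agree with the package's test
    i <- sample(reps, 1)
    expect_equal(rayleigh_test(rad2deg(th[i, ]))$p, p[i], tolerance = 1e-9)
  }
})

test_that("circ_corr matches a direct two-loop evaluation and its bounds", {
  set.seed(3)
  a <- wrap_angle(rnorm(10, 20, 50))
  b <- wrap_angle(rnorm(10, -40, 50))
  got <- circ_corr(a, b)
  # independent brute-force oracle
  abar <- atan2(mean(sin(deg2rad(a))), mean(cos(deg2rad(a))))
  bbar <- atan2(mean(sin(deg2rad(b))), mean(cos(deg2rad(b))))
  num <- 0; da <- 0; db <- 0
  for (i in 1:10) {
    num <- num + sin(deg2rad(a[i]) - abar) * sin(deg2rad(b[i]) - bbar)
    da <- da + sin(deg2rad(a[i]) - abar)^2
    db <- db + sin(deg2rad(b[i]) - bbar)^2
  }
  expect_equal(got$r, num / sqrt(da * db), tolerance = 1e-12)
  expect_equal(got$z, atanh(got$r), tolerance = 1e-12)
  expect_equal(circ_corr(a, a)$r, 1, tolerance = 1e-12)
  expect_equal(circ_corr(a, wrap_angle(-a))$r, -1, tolerance = 1e-12)
  expect_equal(circ_corr(a, b)$r, circ_corr(b, a)$r, tolerance = 1e-12)
  expect_error(circ_corr(a, rep(10, 10)), "degenerate-input")
  expect_error(circ_corr(a[1:2], b[1:2]))
})

test_that("pooled Fisher-Z interval is centered and covers a common dependence", {
  ci0 <- pooled_fisher_ci(rep(0, 8))
  expect_equal(ci0$mean, 0)
  expect_equal(ci0$lower, -ci0$upper, tolerance = 1e-12)
  expect_error(pooled_fisher_ci(0.5), "at least 2")
  expect_error(pooled_fisher_ci(c(1, 0.2)), "infinite-z")

  set.seed(11)
  n_rep <- 500; n_part <- 8; n_tr <- 80
  rs <- matrix(NA_real_, n_rep, n_part)
  for (r in seq_len(n_rep)) for (p in seq_len(n_part)) {
    a <- runif(n_tr, -180, 180)
    b <- wrap_angle(a + rnorm(n_tr, 0, 60))
    rs[r, p] <- circ_corr(a, b)$r
  }
  truth <- tanh(mean(atanh(rs)))     # population value of the pooled statistic
  cover <- mean(vapply(seq_len(n_rep), function(r) {
    ci <- pooled_fisher_ci(rs[r, ])
    ci$lower <= truth && truth <= ci$upper
  }, logical(1)))
  expect_gte(cover, 0.90)
})

test_that("bootstrap_ci is reproducible, leaves the RNG alone, and covers", {
  ci <- bootstrap_ci(rep(3, 20), seed = 5)
  expect_equal(ci$lower, 3)
  expect_equal(ci$upper, 3)
  expect_error(bootstrap_ci(numeric(0), seed = 1), "non-empty")
  expect_error(bootstrap_ci(1:5, n_boot = 10, seed = 1))
  expect_error(bootstrap_ci(1:5))

  x <- rnorm(40)
  set.seed(99); before <- runif(1)
  set.seed(99)
  ci1 <- bootstrap_ci(x, seed = 7)
  expect_identical(runif(1), before)   # caller's stream untouched
  ci2 <- bootstrap_ci(x, seed = 7)
  expect_identical(ci1, ci2)

  set.seed(21)
  n_rep <- 400
  cover <- mean(vapply(seq_len(n_rep), function(r) {
    y <- rnorm(50)
    ci <- bootstrap_ci(y, stat = mean, n_boot = 1000, seed = r)
    ci$lower <= 0 && 0 <= ci$upper
  }, logical(1)))
  expect_gt(cover, 0.90)
  expect_lt(cover, 0.99)
})

test_that("direction_bias is positive toward the internal drift", {
  expect_equal(direction_bias(25, 0, 1), 25)
  expect_equal(direction_bias(-10, 0, -1), 10)
  expect_equal(direction_bias(77, 77, 1), 0)
  expect_equal(direction_bias(77, 77, -1), 0)
  expect_error(direction_bias(10, 0, 0), "internal_sign")
  # consistency at the wrap boundary
  expect_equal(direction_bias(-175, 175, 1), 10)
})

test_that("direction_bias recovers an injected bias in the large-sample limit", {
  set.seed(13)
  n <- 10000
  phys <- runif(n, -180, 180)
  s <- sample(c(-1, 1), n, replace = TRUE)
  beta <- 18
  resp <- wrap_angle(phys + s * beta + rnorm(n, 0, 15))
  expect_equal(as.numeric(angular_mean(direction_bias(resp, phys, s))),
               beta, tolerance = 0.5)
})
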