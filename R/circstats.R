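# Circular-statistical primitives.
#
# Convention used throughout the package: angles are expressed in degrees,
# counterclockwise-positive, measured from the screen's +x axis, with the
# wrapped representative in (-180, 180].  Internally all trigonometry is done
# in radians.

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

#' Wrap an angle into (-180, 180]
#'
#' @param a Numeric vector of angles in degrees.
#' @return Angles in degrees wrapped to the unique representative in
#'   `(-180, 180]`.  `-180` maps to `+180`.
#' @examples
#' wrap_angle(c(190, -180, 45))
#' @export
wrap_angle <- function(a) {
  if (!is.numeric(a) || any(!is.finite(a)))
    stop("invalid-angle: angles must be finite numeric values")
  w <- a %% 360
  w[w > 180] <- w[w > 180] - 360
  # x %% 360 can return 360 - eps or exactly 0 for negative multiples; both
  # already lie in [0, 180].  -180 %% 360 == 180, kept as +180 by convention.
  w
}

#' Signed angular difference a - b
#'
#' @param a,b Angles in degrees.
#' @return The wrapped signed difference `a - b` in degrees, in (-180, 180].
#' @examples
#' ang_diff(350, 10)  # -20
#' @export
ang_diff <- function(a, b) {
  if (any(!is.finite(a)) || any(!is.finite(b)))
    stop("invalid-angle: angles must be finite")
  wrap_angle(a - b)
}

#' Angular (circular) mean
#'
#' Mean direction `atan2(mean sin, mean cos)` of a sample of angles.  The mean
#' resultant length is attached as attribute `"rbar"`; a resultant below
#' `tol` means the mean direction is undefined and an error is raised.
#'
#' @param angles Angles in degrees (non-empty).
#' @param tol Minimum mean resultant length for the mean to be defined.
#' @return Mean direction in degrees, wrapped, with attribute `rbar`.
#' @export
angular_mean <- function(angles, tol = 1e-9) {
  if (length(angles) == 0) stop("angular_mean requires a non-empty sample")
  if (any(!is.finite(angles))) stop("invalid-angle: angles must be finite")
  th <- deg2rad(angles)
  s <- mean(sin(th)); c <- mean(cos(th))
  rbar <- sqrt(s^2 + c^2)
  if (rbar < tol)
    stop("undefined-mean: resultant length below tolerance (", tol, ")")
  m <- wrap_angle(rad2deg(atan2(s, c)))
  attr(m, "rbar") <- rbar
  m
}

#' Mean resultant length
#'
#' @param angles Angles in degrees.
#' @return The mean resultant length, in `[0, 1]`.
#' @export
resultant_length <- function(angles) {
  th <- deg2rad(angles)
  sqrt(mean(sin(th))^2 + mean(cos(th))^2)
}

#' Circular standard deviation
#'
#' `sqrt(-2 log rbar)` converted to degrees.
#'
#' @param angles Angles in degrees.
#' @return Circular SD in degrees.
#' @export
circ_sd <- function(angles) {
  rbar <- resultant_length(angles)
  rad2deg(sqrt(-2 * log(max(rbar, .Machine$double.xmin))))
}

#' Rayleigh test of circular uniformity
#'
#' Tests whether a sample of angles is concentrated around a common direction
#' against the null of circular uniformity.  The statistic is `z = n * rbar^2`
#' and the p-value uses the finite-n approximation
#' `p = exp(sqrt(1 + 4n + 4(n^2 - R^2)) - (1 + 2n))` with `R = n * rbar`.
#'
#' @param angles Angles in degrees, `n >= 2`.
#' @return An object of class `"rayleigh_test"`: a list with `n`, `rbar`,
#'   `z`, and `p`.
#' @export
rayleigh_test <- function(angles) {
  n <- length(angles)
  if (n < 2) stop("rayleigh_test requires at least 2 angles")
  rbar <- resultant_length(angles)
  R <- n * rbar
  z <- n * rbar^2
  p <- exp(sqrt(1 + 4 * n + 4 * (n^2 - R^2)) - (1 + 2 * n))
  p <- min(p, 1)
  structure(list(n = n, rbar = rbar, z = z, p = p), class = "rayleigh_test")
}

#' @export
print.rayleigh_test <- function(x, ...) {
  cat(sprintf("Rayleigh test: n = %d, rbar = %.4f, z = %.4f, p = %.4g\n",
              x$n, x$rbar, x$z, x$p))
  invisible(x)
}

#' Circular-circular correlation (Jammalamadaka-SenGupta)
#'
#' A measure of circular dependence with the same properties as the product
#' moment correlation for linear variables:
#' `r = sum sin(a - abar) sin(b - bbar) / sqrt(sum sin^2(a - abar) * sum sin^2(b - bbar))`
#' where `abar`, `bbar` are the angular means.  `z = atanh(r)` is Fisher's Z.
#'
#' @param a,b Paired angles in degrees, equal length, `n >= 3`.
#' @return An object of class `"circ_corr"`: list with `r`, `z`, `n`.
#' @export
circ_corr <- function(a, b) {
  if (length(a) != length(b)) stop("samples must have equal length")
  n <- length(a)
  if (n < 3) stop("circ_corr requires at least 3 pairs")
  abar <- deg2rad(angular_mean(a))
  bbar <- deg2rad(angular_mean(b))
  sa <- sin(deg2rad(a) - abar)
  sb <- sin(deg2rad(b) - bbar)
  den <- sqrt(sum(sa^2) * sum(sb^2))
  if (den == 0)
    stop("degenerate-input: at least one sample is angularly constant")
  r <- sum(sa * sb) / den
  r <- max(-1, min(1, r))
  z <- if (abs(r) < 1) atanh(r) else sign(r) * Inf
  structure(list(r = r, z = z, n = n), class = "circ_corr")
}

#' @export
print.circ_corr <- function(x, ...) {
  cat(sprintf("Circular correlation: r = %.4f (z = %.4f), n = %d\n",
              x$r, x$z, x$n))
  invisible(x)
}

#' Group confidence interval for correlations via Fisher's Z
#'
#' Per-participant correlation coefficients are transformed with `atanh`,
#' a t-based confidence interval (n - 1 df) is computed for their mean, and
#' the bounds are back-transformed with `tanh`.
#'
#' @param rs Correlation coefficients, one per participant, all `|r| < 1`,
#'   at least 2.
#' @param level Confidence level (default 0.95).
#' @return List with `mean` (back-transformed mean), `lower`, `upper`,
#'   `level`, `n`.
#' @export
pooled_fisher_ci <- function(rs, level = 0.95) {
  if (length(rs) < 2)
    stop("pooled_fisher_ci requires at least 2 participants")
  if (any(abs(rs) >= 1))
    stop("infinite-z: |r| = 1 cannot be Fisher-transformed")
  z <- atanh(rs)
  n <- length(z)
  m <- mean(z)
  se <- stats::sd(z) / sqrt(n)
  q <- stats::qt(1 - (1 - level) / 2, df = n - 1)
  list(mean = tanh(m), lower = tanh(m - q * se), upper = tanh(m + q * se),
       level = level, n = n)
}

#' Bootstrap percentile confidence interval
#'
#' Resamples `values` with replacement `n_boot` times, applies `stat`, and
#' returns the percentile interval.  The seed is mandatory and the caller's
#' RNG state is left untouched.
#'
#' @param values Non-empty vector of values (e.g. per-trial direction biases).
#' @param stat Function mapping a vector to a scalar statistic.
#' @param n_boot Number of resamples, at least 100.
#' @param level Confidence level.
#' @param seed Integer seed (required for reproducibility).
#' @return List with `lower`, `upper`, `level`, `n_boot`, and `stat0`
#'   (statistic on the original sample).
#' @export
bootstrap_ci <- function(values, stat = mean, n_boot = 2000, level = 0.95,
                         seed) {
  if (length(values) == 0) stop("bootstrap_ci requires a non-empty sample")
  if (n_boot < 100) stop("n_boot must be at least 100")
  if (missing(seed)) stop("seed is required")
  reps <- with_local_rng(seed, {
    vapply(seq_len(n_boot), function(i) {
      stat(values[sample.int(length(values), replace = TRUE)])
    }, numeric(1))
  })
  alpha <- (1 - level) / 2
  qs <- stats::quantile(reps, c(alpha, 1 - alpha), names = FALSE, type = 7)
  list(lower = qs[1], upper = qs[2], level = level, n_boot = n_boot,
       stat0 = stat(values))
}

# Evaluate `expr` under a private RNG stream seeded with `seed`, restoring
# the caller's .Random.seed afterwards.
with_local_rng <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Direction bias of a response toward the internal drift
#'
#' Signed angular deviation of a response from the physical motion direction,
#' oriented so that positive values indicate deviation toward the direction of
#' the internal motion (the convention in which the physical direction is at
#' 0 degrees and the internal drift at +90 degrees).
#'
#' @param response Response direction in degrees.
#' @param physical Physical (envelope) motion direction in degrees.
#' @param internal_sign `+1` if the internal drift is at `physical + 90`,
#'   `-1` if at `physical - 90`.
#' @return Bias in degrees; positive = toward the internal drift.
#' @export
direction_bias <- function(response, physical, internal_sign) {
  if (!all(internal_sign %in% c(-1, 1)))
    stop("internal_sign must be +1 or -1")
  internal_sign * ang_diff(response, physical)
}
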