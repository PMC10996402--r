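# 1/f-noise stimulus movies.
#
# Double-drift movies are square snapshots from a single 2D surface of 1/f
# luminance noise, each snapshot shifted a constant number of pixels from the
# previous one along a constant direction.  Control movies are successive
# depth slices of a 3D volume of 1/f noise (half-pixel depth steps supported
# by linear interpolation), so their texture changes at a matched rate but
# carries no net motion.  Every frame is multiplied by a 2D Gaussian contrast
# envelope.

# Spectrally shaped noise: white Gaussian noise whose Fourier amplitudes are
# scaled by 1/f (DC set to zero), normalized to zero mean, unit variance.
noise_field <- function(dims) {
  freq_axis <- function(n) {
    f <- c(seq(0, floor(n / 2)), seq(-ceiling(n / 2) + 1, -1)) / n
    f
  }
  w <- array(stats::rnorm(prod(dims)), dim = dims)
  W <- stats::fft(w)
  grids <- lapply(dims, freq_axis)
  f2 <- array(0, dim = dims)
  for (d in seq_along(dims))
    f2 <- f2 + outer_axis(grids[[d]]^2, d, dims)
  f <- sqrt(f2)
  amp <- ifelse(f > 0, 1 / f, 0)
  x <- Re(stats::fft(W * amp, inverse = TRUE)) / prod(dims)
  x <- x - mean(x)
  x / stats::sd(x)
}

# Broadcast a per-axis vector v along axis `d` of an array of size `dims`.
outer_axis <- function(v, d, dims) {
  perm <- seq_along(dims)
  perm[c(1, d)] <- perm[c(d, 1)]
  a <- array(v, dim = dims[perm])
  if (d == 1) a else aperm(a, order(perm))
}

#' Generate a 1/f-noise stimulus movie
#'
#' @param kind `"drift"` (constant texture shift per frame) or `"control"`
#'   (depth slices of a 3D 1/f volume; no net motion).
#' @param shift_px Texture shift per frame in pixels (drift), or depth step
#'   per frame in voxels (control; 0.5 interpolates between slices).
#' @param n_frames Number of frames (>= 2).
#' @param patch_px Side of the square patch in pixels (>= 32).
#' @param envelope_sd Gaussian envelope SD, dva.
#' @param px_per_dva Pixels per degree of visual angle.
#' @param frame_rate Frames per second.
#' @return An object of class `"noise_movie"`: list with `frames` (enveloped
#'   matrices in a list), `texture` (pre-envelope snapshots), `envelope`,
#'   `kind`, `shift_px`, `px_per_dva`, `frame_rate`.  Uses the current RNG
#'   stream.
#' @export
make_noise_movie <- function(kind = c("drift", "control"), shift_px = 2,
                             n_frames = 24, patch_px = 64,
                             envelope_sd = 0.35, px_per_dva = 30.5,
                             frame_rate = 120) {
  kind <- match.arg(kind)
  if (patch_px < 32) stop("patch_px must be at least 32")
  if (n_frames < 2) stop("n_frames must be at least 2")

  if (kind == "drift") {
    total_shift <- ceiling(abs(shift_px) * (n_frames - 1))
    side <- 4 * patch_px
    if (patch_px + total_shift > side)
      stop("total shift larger than the source field")
    field <- noise_field(c(side, side))
    texture <- lapply(seq_len(n_frames) - 1L, function(k) {
      off <- round(k * shift_px)
      field[seq_len(patch_px) + off, seq_len(patch_px), drop = FALSE]
    })
  } else {
    depth_needed <- (n_frames - 1) * shift_px
    nz <- max(16, ceiling(depth_needed) + 2)
    side <- 2 * patch_px
    vol <- noise_field(c(side, side, nz))
    texture <- lapply(seq_len(n_frames) - 1L, function(k) {
      z <- 1 + k * shift_px
      z0 <- floor(z); w <- z - z0
      sl <- vol[seq_len(patch_px), seq_len(patch_px), z0]
      if (w > 0)
        sl <- (1 - w) * sl + w * vol[seq_len(patch_px), seq_len(patch_px),
                                     z0 + 1]
      sl
    })
  }

  # contrast normalization: drift and control stacks get identical marginal
  # pixel statistics, emulating the matched-contrast stimuli
  mu <- mean(unlist(texture)); sg <- stats::sd(unlist(texture))
  texture <- lapply(texture, function(tx) (tx - mu) / sg)

  ctr <- (patch_px + 1) / 2
  d2 <- outer(seq_len(patch_px) - ctr, seq_len(patch_px) - ctr,
              function(i, j) i^2 + j^2)
  env <- exp(-d2 / (2 * (envelope_sd * px_per_dva)^2))
  frames <- lapply(texture, function(tx) tx * env)

  structure(list(frames = frames, texture = texture, envelope = env,
                 kind = kind, shift_px = shift_px, px_per_dva = px_per_dva,
                 frame_rate = frame_rate),
            class = "noise_movie")
}

#' Write a noise movie as a multi-page TIFF
#'
#' Frames are jointly rescaled to [0, 1] around mid-gray.
#'
#' @param movie A [make_noise_movie()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
movie_to_tiff <- function(movie, path) {
  mx <- max(abs(unlist(movie$frames)))
  pages <- lapply(movie$frames, function(f) {
    pmin(pmax(0.5 + f / (2 * mx), 0), 1)
  })
  tiff::writeTIFF(pages, path)
  invisible(path)
}

#' Estimate inter-frame displacement by phase correlation
#'
#' Cross-correlates two frames in the Fourier domain (whitened spectra) and
#' returns the displacement of the correlation peak, in pixels, of the second
#' frame relative to the first along each image axis.
#'
#' @param a,b Two matrices of equal size.
#' @return Integer vector `c(d_row, d_col)`; displacements beyond half the
#'   image size wrap to negative values.
#' @export
phase_displacement <- function(a, b) {
  stopifnot(all(dim(a) == dim(b)))
  Fa <- stats::fft(a); Fb <- stats::fft(b)
  R <- Fa * Conj(Fb)
  mag <- Mod(R)
  R <- R / ifelse(mag > 0, mag, 1)
  xc <- Re(stats::fft(R, inverse = TRUE))
  pk <- which(xc == max(xc), arr.ind = TRUE)[1, ]
  d <- pk - 1
  n <- dim(a)
  d <- ifelse(d > n / 2, d - n, d)
  -as.numeric(d)
}

#' Radial amplitude-spectrum slope of a noise field
#'
#' Fits a line to the log-log radially binned amplitude spectrum; a 1/f field
#' has slope close to -1.
#'
#' @param field A square matrix.
#' @param f_range Frequency range (cycles/pixel) used for the fit.
#' @return The fitted slope.
#' @export
spectral_slope <- function(field, f_range = c(0.01, 0.25)) {
  n <- nrow(field)
  A <- Mod(stats::fft(field))
  fx <- c(seq(0, floor(n / 2)), seq(-ceiling(n / 2) + 1, -1)) / n
  f <- sqrt(outer(fx^2, fx^2, `+`))
  keep <- f >= f_range[1] & f <= f_range[2]
  bins <- cut(log10(f[keep]), breaks = 24)
  lf <- tapply(log10(f[keep]), bins, mean)
  la <- tapply(log10(A[keep]), bins, mean)
  ok <- is.finite(lf) & is.finite(la)
  unname(stats::coef(stats::lm(la[ok] ~ lf[ok]))[2])
}
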