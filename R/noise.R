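#' Catmull-Rom basis weights
#'
#' Weights of the four control points surrounding an interpolation phase
#' `x` in \[0, 1\] (x = 0 at the second control point, 1 at the third), for the
#' interpolating cubic spline with zero local tension and C1 continuity.
#'
#' @param x numeric vector of phases in \[0, 1\].
#' @return `length(x) x 4` matrix of weights; each row sums to 1.
#' @export
catmull_rom_weights <- function(x) {
  x2 <- x * x
  x3 <- x2 * x
  cbind(-0.5 * x3 + x2 - 0.5 * x,
        1.5 * x3 - 2.5 * x2 + 1,
        -1.5 * x3 + 2 * x2 + 0.5 * x,
        0.5 * x3 - 0.5 * x2)
}

#' Catmull-Rom interpolation kernel
#'
#' The cardinal reconstruction kernel of Catmull-Rom interpolation (the cubic
#' convolution kernel with parameter -1/2), supported on \[-2, 2\].
#'
#' @param x numeric vector (in units of the control-point spacing).
#' @return kernel values.
#' @export
catmull_rom_kernel <- function(x) {
  a <- abs(x)
  ifelse(a <= 1, (1.5 * a - 2.5) * a * a + 1,
         ifelse(a < 2, ((-0.5 * a + 2.5) * a - 4) * a + 2, 0))
}

#' -3 dB frequency of Catmull-Rom interpolation
#'
#' Numerically computes the normalized frequency (in units of the
#' control-point sampling rate) at which the squared magnitude response of the
#' Catmull-Rom interpolation kernel falls to half its zero-frequency value.
#' The result, about 0.40449, is the constant used to choose the up-sampling
#' factor for a desired noise cut-off frequency.
#'
#' @param dx quadrature step for the kernel Fourier transform.
#' @param df frequency grid resolution.
#' @return the -3 dB normalized frequency.
#' @export
catmull_rom_minus3db <- function(dx = 1e-4, df = 1e-6) {
  x <- seq(0, 2, by = dx)
  k <- catmull_rom_kernel(x)
  gain <- function(f) {
    # kernel is even: K(f) = 2 * int_0^2 k(x) cos(2 pi f x) dx (trapezoid)
    vapply(f, function(ff) {
      integrand <- k * cos(2 * pi * ff * x)
      2 * (sum(integrand) - (integrand[1] + integrand[length(x)]) / 2) * dx
    }, 0)
  }
  g0 <- gain(0)
  target <- g0^2 / 2
  lo <- 0.3; hi <- 0.5
  while (hi - lo > df) {
    mid <- (lo + hi) / 2
    if (gain(mid)^2 > target) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Spline up-sampling factor for a target cut-off frequency
#'
#' `u = round(0.40449 / (dt * f_cut))`: interpolating Gaussian control points
#' sampled every `u` time steps attenuates power by 3 dB at `f_cut`.
#'
#' @param dt time step (s).
#' @param f_cut intended -3 dB frequency (Hz).
#' @return integer up-sampling factor (>= 1).
#' @export
spline_upsampling <- function(dt, f_cut) {
  if (f_cut <= 0) stop("'f_cut' must be > 0")
  u <- as.integer(round(0.40449 / (dt * f_cut)))
  if (u < 1) stop("up-sampling factor < 1; f_cut too high for this time step")
  u
}

#' Variance calibration factor of Catmull-Rom interpolated white noise
#'
#' Mean output variance of unit-variance i.i.d. control points, averaged over
#' interpolation phases: the integral over one segment of the sum of squared
#' basis weights. Innovations are scaled by `1/sqrt()` of this so the
#' interpolated series has the requested standard deviation.
#'
#' @param n_phases quadrature resolution.
#' @return mean variance factor (about 0.77).
#' @export
catmull_rom_variance_factor <- function(n_phases = 10000) {
  x <- (seq_len(n_phases) - 0.5) / n_phases
  w <- catmull_rom_weights(x)
  mean(rowSums(w * w))
}

#' Band-limited noise by Catmull-Rom interpolation of Gaussian control points
#'
#' Gaussian white innovations are drawn every `u = round(0.40449/(dt*f_cut))`
#' steps and interpolated with a Catmull-Rom spline, giving a C1-continuous
#' series with -3 dB power at `f_cut`, mean `mean` and standard deviation `sd`
#' (innovations are scaled by the numerically computed variance factor).
#'
#' @param mean target mean of the series.
#' @param sd target standard deviation (sd <= 0 gives a constant series).
#' @param f_cut intended -3 dB frequency (Hz).
#' @param dt time step (s).
#' @param n_steps series length.
#' @param seed optional RNG seed (set.seed is called if given).
#' @param n_series number of independent series (columns).
#' @return `n_steps x n_series` matrix.
#' @export
generate_spline_noise <- function(mean, sd, f_cut, dt, n_steps, seed = NULL,
                                  n_series = 1) {
  if (!is.null(seed)) set.seed(seed)
  if (sd <= 0) return(matrix(mean, n_steps, n_series))
  u <- spline_upsampling(dt, f_cut)
  ctrl <- noise_control_points(sd, u, n_steps, n_series)
  mean + interpolate_control_points(ctrl, u, n_steps)
}

# innovations for spline noise: (segments + 3) x n_series, already scaled so
# the interpolated series has standard deviation 'sd'
noise_control_points <- function(sd, u, n_steps, n_series) {
  n_seg <- floor((n_steps - 1) / u) + 1L
  scale <- sd / sqrt(catmull_rom_variance_factor())
  matrix(stats::rnorm((n_seg + 3L) * n_series, 0, scale), n_seg + 3L, n_series)
}

# reconstruct the full series from control points; control row m+1 holds the
# point one segment before the start (phase index m = -1)
interpolate_control_points <- function(ctrl, u, n_steps) {
  n_series <- ncol(ctrl)
  out <- matrix(0, n_steps, n_series)
  s <- seq_len(n_steps) - 1L
  m <- s %/% u
  ph <- (s %% u) / u
  for (x_idx in unique(s %% u)) {
    rows <- which(s %% u == x_idx)
    w <- catmull_rom_weights(ph[rows[1]])
    mm <- m[rows]
    out[rows, ] <- w[1] * ctrl[mm + 1L, , drop = FALSE] +
      w[2] * ctrl[mm + 2L, , drop = FALSE] +
      w[3] * ctrl[mm + 3L, , drop = FALSE] +
      w[4] * ctrl[mm + 4L, , drop = FALSE]
  }
  out
}
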