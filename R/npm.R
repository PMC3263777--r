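#' Neural population model parameters
#'
#' Parameters of the two-population (excitatory e, inhibitory i) mean-field
#' model solved at every mesh vertex. Pair subscripts are source-first: `ee`
#' means e onto e. The defaults are a documented plausible set for this model
#' family, chosen to have a stable resting fixed point with a damped ~8 Hz
#' resonance, so that band-limited noise drives realistic fluctuations; they
#' are not fitted to any particular recording.
#'
#' @param tau membrane time constants (s), named e/i.
#' @param h_rest resting potentials (mV), named e/i.
#' @param h_eq synaptic reversal (Nernst) potentials (mV) per pair.
#' @param Q peak PSP amplitudes (mV) per pair.
#' @param delta PSP rise times to peak (s) per pair.
#' @param eps PSP decay prolongation factors (dimensionless) per pair; 0 gives
#'   the alpha kernel.
#' @param S_max maximal firing rates (1/s), named e/i.
#' @param mu sigmoid midpoints (mV), named e/i.
#' @param sigma sigmoid slopes (mV), named e/i.
#' @param N_alpha local (intracortical) synapse counts per pair.
#' @param N_beta long-range synapse counts at each target vertex, named ee/ei
#'   (long-range connections are excitatory only).
#' @param p_ee_mean mean extracortical input rate to the ee channel (1/s).
#' @param p_ee_sd standard deviation of the noise input (1/s).
#' @param f_cut -3 dB frequency of the noise drive (Hz).
#' @param f_cut_transmission -3 dB frequency of splined rate transmission (Hz);
#'   1.6 kHz gives up-sampling u = 5 at the default time step.
#' @param dt integration time step (s).
#' @return an `npm_parameters` list.
#' @export
npm_parameters <- function(tau = c(e = 0.094, i = 0.042),
                           h_rest = c(e = -70, i = -70),
                           h_eq = c(ee = 45, ei = 45, ie = -90, ii = -90),
                           Q = c(ee = 0.71, ei = 0.71, ie = 0.71, ii = 0.71),
                           delta = c(ee = 1 / 300, ei = 1 / 300,
                                     ie = 1 / 65, ii = 1 / 65),
                           eps = c(ee = 0, ei = 0, ie = 0, ii = 0),
                           S_max = c(e = 500, i = 500),
                           mu = c(e = -50, i = -50),
                           sigma = c(e = 5, i = 5),
                           N_alpha = c(ee = 615, ei = 4582, ie = 2500, ii = 535),
                           N_beta = c(ee = 4000, ei = 2000),
                           p_ee_mean = 2000, p_ee_sd = 500,
                           f_cut = 75, f_cut_transmission = 1600,
                           dt = 5e-5) {
  stopifnot(all(tau > 0), all(delta > 0), all(S_max > 0), all(eps >= 0),
            all(sigma > 0), dt > 0, f_cut > 0)
  p <- list(tau = tau, h_rest = h_rest, h_eq = h_eq, Q = Q, delta = delta,
            eps = eps, S_max = S_max, mu = mu, sigma = sigma,
            N_alpha = N_alpha, N_beta = N_beta, p_ee_mean = p_ee_mean,
            p_ee_sd = p_ee_sd, f_cut = f_cut,
            f_cut_transmission = f_cut_transmission, dt = dt)
  class(p) <- "npm_parameters"
  p
}

#' @export
print.npm_parameters <- function(x, ...) {
  cat("npm_parameters: two-population mean-field model\n")
  cat(sprintf("  tau_e/i = %g/%g s, rest %g/%g mV, dt = %g s\n",
              x$tau["e"], x$tau["i"], x$h_rest["e"], x$h_rest["i"], x$dt))
  cat(sprintf("  noise: p_ee = %g +- %g 1/s, f_cut = %g Hz\n",
              x$p_ee_mean, x$p_ee_sd, x$f_cut))
  invisible(x)
}

#' Sigmoid firing-rate function
#'
#' `S(h) = S_max / (1 + exp(-sqrt(2) (h - mu) / sigma))`: strictly increasing,
#' bounded in (0, S_max), equal to `S_max/2` at the midpoint `mu`.
#'
#' @param h membrane potential (mV); vectorized.
#' @param S_max maximal rate (1/s).
#' @param mu midpoint (mV).
#' @param sigma slope parameter (mV).
#' @return firing rate (1/s).
#' @export
sigmoid_rate <- function(h, S_max, mu, sigma) {
  S_max / (1 + exp(-sqrt(2) * (h - mu) / sigma))
}

# per-pair second-order kernel coefficients: rates g1 (rise), g2 (decay) and
# the drive amplitude 'camp' such that the impulse response peaks at Q.
# eps = 0 is the critically damped alpha kernel; eps > 0 a bi-exponential
# with the decay rate divided by (1 + eps), peak amplitude held at Q.
psp_kernel_coefs <- function(Q, delta, eps) {
  g1 <- 1 / delta
  g2 <- ifelse(eps > 0, 1 / (delta * (1 + eps)), g1)
  camp <- numeric(length(Q))
  for (p in seq_along(Q)) {
    if (eps[p] > 1e-12) {
      tp <- log(g1[p] / g2[p]) / (g1[p] - g2[p])
      peak <- exp(-g2[p] * tp) - exp(-g1[p] * tp)
      camp[p] <- Q[p] * (g1[p] - g2[p]) / peak
    } else {
      camp[p] <- exp(1) * Q[p] * g1[p]
    }
  }
  list(g1 = g1, g2 = g2, camp = camp)
}

#' PSP impulse response
#'
#' Response of the synaptic kernel to a pre-synaptic Dirac pulse. For
#' `eps = 0` the alpha form `Q e (t/delta) exp(-t/delta)`: zero at `t = 0`,
#' single maximum `Q` at `t = delta` (the rise time). For `eps > 0` a
#' bi-exponential whose decay rate is divided by `1 + eps`, renormalized so
#' the peak amplitude stays `Q`; continuous in `eps` at 0.
#'
#' @param Q peak amplitude (mV).
#' @param delta rise time (s).
#' @param eps decay prolongation (>= 0).
#' @param t time since the pulse (s), >= 0; vectorized.
#' @return PSP amplitude (mV).
#' @export
psp_impulse_response <- function(Q, delta, eps, t) {
  if (delta <= 0) stop("'delta' must be > 0")
  if (any(t < 0)) stop("'t' must be >= 0")
  co <- psp_kernel_coefs(Q, delta, eps)
  if (eps > 1e-12) {
    co$camp / (co$g1 - co$g2) * (exp(-co$g2 * t) - exp(-co$g1 * t))
  } else {
    Q * exp(1) * (t / delta) * exp(-t / delta)
  }
}

# synaptic activations A_lk at membrane potentials (h_e, h_i); 'gain' is the
# total long-range weight per target (background sums to 1)
npm_activations <- function(h, params, gain = 1, p_ee = params$p_ee_mean) {
  se <- sigmoid_rate(h[1], params$S_max["e"], params$mu["e"], params$sigma["e"])
  si <- sigmoid_rate(h[2], params$S_max["i"], params$mu["i"], params$sigma["i"])
  c(ee = unname(params$N_alpha["ee"] * se + p_ee + params$N_beta["ee"] * gain * se),
    ei = unname(params$N_alpha["ei"] * se + params$N_beta["ei"] * gain * se),
    ie = unname(params$N_alpha["ie"] * si),
    ii = unname(params$N_alpha["ii"] * si))
}

# membrane equation residuals at steady state (I_lk = e Q delta A_lk)
npm_residual <- function(h, params, gain = 1, p_ee = params$p_ee_mean) {
  A <- npm_activations(h, params, gain, p_ee)
  I <- exp(1) * params$Q * params$delta * A
  psi_den <- abs(params$h_eq - params$h_rest[c("e", "i", "e", "i")])
  c(params$h_rest["e"] - h[1] +
      (params$h_eq["ee"] - h[1]) / psi_den["ee"] * I["ee"] +
      (params$h_eq["ie"] - h[1]) / psi_den["ie"] * I["ie"],
    params$h_rest["i"] - h[2] +
      (params$h_eq["ei"] - h[2]) / psi_den["ei"] * I["ei"] +
      (params$h_eq["ii"] - h[2]) / psi_den["ii"] * I["ii"])
}

#' Resting fixed point of the single-vertex model
#'
#' Newton iteration (numerical Jacobian) on the two stationary membrane
#' equations; the PSP states are eliminated analytically at steady state.
#'
#' @param params an [npm_parameters()] set.
#' @param long_range_gain total long-range input weight per target vertex
#'   (1 for pure background connectivity, 0 for an isolated vertex).
#' @param h0 starting guess `(h_e, h_i)` (mV).
#' @param tol convergence tolerance on the Newton step (mV).
#' @return list with `h_e`, `h_i`, steady `I` (mV) and `A` (1/s) per pair,
#'   rates `s_e`, `s_i` (1/s), and the residual.
#' @export
npm_fixed_point <- function(params, long_range_gain = 1,
                            h0 = unname(params$h_rest), tol = 1e-12) {
  h <- h0
  for (it in 1:500) {
    r <- npm_residual(h, params, long_range_gain)
    J <- matrix(0, 2, 2)
    de <- 1e-6
    for (j in 1:2) {
      hp <- h; hp[j] <- hp[j] + de
      J[, j] <- (npm_residual(hp, params, long_range_gain) - r) / de
    }
    step <- solve(J, -r)
    step <- pmax(pmin(step, 5), -5)
    h <- h + step
    if (max(abs(step)) < tol) break
  }
  A <- npm_activations(h, params, long_range_gain)
  I <- exp(1) * params$Q * params$delta * A
  list(h_e = unname(h[1]), h_i = unname(h[2]), I = I, A = A,
       s_e = sigmoid_rate(h[1], params$S_max["e"], params$mu["e"], params$sigma["e"]),
       s_i = sigmoid_rate(h[2], params$S_max["i"], params$mu["i"], params$sigma["i"]),
       residual = npm_residual(h, params, long_range_gain))
}

#' Linear stability of the single-vertex fixed point
#'
#' Eigenvalues of the 10-dimensional Jacobian (2 membrane potentials plus four
#' second-order PSP states) at the fixed point, ignoring conduction delays.
#'
#' @inheritParams npm_fixed_point
#' @return list with `eigenvalues` (sorted by real part, decreasing),
#'   `max_re` and `stable`.
#' @export
npm_stability <- function(params, long_range_gain = 1) {
  fp <- npm_fixed_point(params, long_range_gain)
  co <- psp_kernel_coefs(params$Q, params$delta, params$eps)
  psi_den <- abs(params$h_eq - params$h_rest[c("e", "i", "e", "i")])
  f <- function(s) {
    h <- s[1:2]; I <- s[3:6]; Jv <- s[7:10]
    A <- npm_activations(h, params, long_range_gain)
    dh <- c((params$h_rest["e"] - h[1] +
               (params$h_eq["ee"] - h[1]) / psi_den["ee"] * I[1] +
               (params$h_eq["ie"] - h[1]) / psi_den["ie"] * I[3]) / params$tau["e"],
            (params$h_rest["i"] - h[2] +
               (params$h_eq["ei"] - h[2]) / psi_den["ei"] * I[2] +
               (params$h_eq["ii"] - h[2]) / psi_den["ii"] * I[4]) / params$tau["i"])
    c(dh, Jv, -(co$g1 + co$g2) * Jv - co$g1 * co$g2 * I + co$camp * A)
  }
  s0 <- c(fp$h_e, fp$h_i, unname(fp$I), rep(0, 4))
  J <- matrix(0, 10, 10)
  f0 <- f(s0)
  for (j in 1:10) {
    sp <- s0; sp[j] <- sp[j] + 1e-6
    J[, j] <- (f(sp) - f0) / 1e-6
  }
  ev <- eigen(J, only.values = TRUE)$values
  ev <- ev[order(-Re(ev))]
  list(eigenvalues = ev, max_re = max(Re(ev)), stable = max(Re(ev)) < 0)
}

#' One forward-Euler step of the per-vertex population equations
#'
#' Advances membrane potentials and PSP kernel states by one time step, given
#' the consumed long-range inputs and the extracortical drive. This is the
#' reference form of the update rule used (in compiled form) by
#' [run_simulation()]; exposed for inspection, single-vertex experiments and
#' tests.
#'
#' @param state list with `h_e`, `h_i` (length n) and `I`, `J` (n x 4 matrices,
#'   pair order ee/ei/ie/ii).
#' @param params an [npm_parameters()] set.
#' @param phi per-vertex consumed long-range input (weighted delayed e-rates,
#'   before the `N_beta` multiplier).
#' @param p_ee per-vertex extracortical drive (1/s).
#' @param dt time step (s); defaults to `params$dt`.
#' @return list with the updated `state` and the activations `A` used.
#' @export
step_state <- function(state, params, phi = 0, p_ee = params$p_ee_mean,
                       dt = params$dt) {
  h_e <- state$h_e; h_i <- state$h_i; I <- state$I; J <- state$J
  n <- length(h_e)
  if (any(!is.finite(c(h_e, h_i)))) stop("non-finite membrane potential")
  phi <- rep_len(phi, n); p_ee <- rep_len(p_ee, n)
  se <- sigmoid_rate(h_e, params$S_max["e"], params$mu["e"], params$sigma["e"])
  si <- sigmoid_rate(h_i, params$S_max["i"], params$mu["i"], params$sigma["i"])
  A <- cbind(params$N_alpha["ee"] * se + p_ee + params$N_beta["ee"] * phi,
             params$N_alpha["ei"] * se + params$N_beta["ei"] * phi,
             params$N_alpha["ie"] * si,
             params$N_alpha["ii"] * si)
  psi_den <- abs(params$h_eq - params$h_rest[c("e", "i", "e", "i")])
  co <- psp_kernel_coefs(params$Q, params$delta, params$eps)
  h_e_new <- h_e + dt * ((params$h_rest["e"] - h_e +
               (params$h_eq["ee"] - h_e) / psi_den["ee"] * I[, 1] +
               (params$h_eq["ie"] - h_e) / psi_den["ie"] * I[, 3]) / params$tau["e"])
  h_i_new <- h_i + dt * ((params$h_rest["i"] - h_i +
               (params$h_eq["ei"] - h_i) / psi_den["ei"] * I[, 2] +
               (params$h_eq["ii"] - h_i) / psi_den["ii"] * I[, 4]) / params$tau["i"])
  I_new <- I + dt * J
  J_new <- J + dt * (-sweep(J, 2, co$g1 + co$g2, "*") -
                     sweep(I, 2, co$g1 * co$g2, "*") +
                     sweep(A, 2, co$camp, "*"))
  list(state = list(h_e = unname(h_e_new), h_i = unname(h_i_new),
                    I = I_new, J = J_new),
       A = A)
}
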