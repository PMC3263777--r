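#' Balloon-windkessel parameters
#'
#' Canonical haemodynamic parameter set: vasodilatory signal decay rate
#' `kappa`, flow autoregulation rate `gamma_f`, mean transit time `tau0`,
#' vessel stiffness exponent `alpha`, resting oxygen extraction `E0`, resting
#' venous blood volume fraction `V0`, and the three BOLD observation
#' coefficients `k1 = 7 E0`, `k2 = 2`, `k3 = 2 E0 - 0.2`. The neural drive is
#' the excitatory-input sum `f_e * A_ee + (1 - f_e) * A_ei` (glutamate-release
#' proxy), baseline-subtracted and scaled by `drive_scale`.
#'
#' @param kappa signal decay rate (1/s).
#' @param gamma_f autoregulation rate (1/s).
#' @param tau0 transit time (s).
#' @param alpha stiffness exponent.
#' @param E0 resting oxygen extraction fraction, in (0, 1).
#' @param V0 resting venous volume fraction.
#' @param f_e fraction of excitatory neurons (default 0.85).
#' @param drive_scale scaling constant from relative excitatory-input
#'   deviation to the dimensionless drive z.
#' @param dt_h haemodynamic integration step (s); the neural drive is held
#'   piecewise-constant between its samples.
#' @return a `balloon_parameters` list (includes k1, k2, k3).
#' @export
balloon_parameters <- function(kappa = 0.65, gamma_f = 0.41, tau0 = 0.98,
                               alpha = 0.32, E0 = 0.34, V0 = 0.02,
                               f_e = 0.85, drive_scale = 1, dt_h = 1e-3) {
  stopifnot(kappa > 0, gamma_f > 0, tau0 > 0, alpha > 0, E0 > 0, E0 < 1,
            V0 > 0, f_e >= 0, f_e <= 1, dt_h > 0)
  structure(list(kappa = kappa, gamma_f = gamma_f, tau0 = tau0, alpha = alpha,
                 E0 = E0, V0 = V0, f_e = f_e, drive_scale = drive_scale,
                 dt_h = dt_h, k1 = 7 * E0, k2 = 2, k3 = 2 * E0 - 0.2),
            class = "balloon_parameters")
}

#' Neural drive for the haemodynamic model
#'
#' `z = drive_scale * (f_e A_ee + (1 - f_e) A_ei - baseline) / baseline`:
#' only excitatory synaptic inputs drive the BOLD response, weighted by the
#' excitatory/inhibitory neuron fractions, with the resting baseline
#' subtracted so that `z = 0` at rest.
#'
#' @param A_ee,A_ei excitatory synaptic activation onto e and i populations
#'   (1/s); vectors or `n x time` matrices.
#' @param pars a [balloon_parameters()].
#' @param baseline resting value of `f_e A_ee + (1 - f_e) A_ei`, e.g. from
#'   [npm_fixed_point()]; used both to subtract and to normalize.
#' @return drive z, same shape as the inputs.
#' @export
neural_drive <- function(A_ee, A_ei, pars, baseline) {
  if (baseline <= 0) stop("'baseline' must be > 0")
  raw <- pars$f_e * A_ee + (1 - pars$f_e) * A_ei
  pars$drive_scale * (raw - baseline) / baseline
}

# derivative of the four-state balloon system; state columns s, f, v, q
balloon_deriv <- function(state, z, pars) {
  s <- state[, 1]; f <- state[, 2]; v <- state[, 3]; q <- state[, 4]
  E <- 1 - (1 - pars$E0)^(1 / f)
  vexp <- v^(1 / pars$alpha)
  cbind(z - pars$kappa * s - pars$gamma_f * (f - 1),
        s,
        (f - vexp) / pars$tau0,
        (f * E / pars$E0 - vexp * q / v) / pars$tau0)
}

#' One haemodynamic integration step (RK4)
#'
#' Advances the four balloon-windkessel ODEs (vasodilatory signal, inflow,
#' venous volume, deoxyhaemoglobin) by `dt` with the drive held constant.
#'
#' @param state `n x 4` matrix, columns (s, f, v, q); baseline (0, 1, 1, 1).
#' @param z drive per vertex.
#' @param pars a [balloon_parameters()].
#' @param dt step (s).
#' @return updated state matrix.
#' @export
balloon_step <- function(state, z, pars, dt) {
  k1 <- balloon_deriv(state, z, pars)
  k2 <- balloon_deriv(state + dt / 2 * k1, z, pars)
  k3 <- balloon_deriv(state + dt / 2 * k2, z, pars)
  k4 <- balloon_deriv(state + dt * k3, z, pars)
  out <- state + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  if (any(out[, 3] <= 0) || any(!is.finite(out)))
    stop("balloon state underflow/divergence (volume <= 0 or non-finite)")
  out
}

#' BOLD signal from the balloon state
#'
#' Standard three-term observation equation
#' `y = V0 (k1 (1 - q) + k2 (1 - q/v) + k3 (1 - v))`; zero at the resting
#' fixed point (baseline already subtracted by construction).
#'
#' @param state `n x 4` state matrix.
#' @param pars a [balloon_parameters()].
#' @return BOLD contrast per vertex.
#' @export
bold_signal <- function(state, pars) {
  v <- state[, 3]; q <- state[, 4]
  pars$V0 * (pars$k1 * (1 - q) + pars$k2 * (1 - q / v) + pars$k3 * (1 - v))
}

#' Resting state of the balloon model
#'
#' Locates the fixed point for a constant drive `z0` numerically (damped
#' fixed-point iteration on the stationary equations). For `z0 = 0` this is
#' exactly (0, 1, 1, 1).
#'
#' @param pars a [balloon_parameters()].
#' @param z0 constant drive.
#' @return length-4 state vector.
#' @export
balloon_rest <- function(pars, z0 = 0) {
  s <- z0 / pars$kappa * 0                 # stationary s solves z = kappa s -> but
  f <- 1 + z0 / pars$gamma_f               # ds=0, df=0 => s=0, f = 1 + z/gamma
  v <- f^pars$alpha
  E <- 1 - (1 - pars$E0)^(1 / f)
  q <- f * E / pars$E0 / v^(1 / pars$alpha) * v
  c(s = 0, f = unname(f), v = unname(v), q = unname(q))
}

#' Simulate BOLD from recorded synaptic activations
#'
#' Integrates the balloon model at step `pars$dt_h` (RK4), with the neural
#' drive held piecewise-constant between the recorded samples, and returns the
#' BOLD contrast decimated to `output_dt`.
#'
#' @param A_ee,A_ei `n x nt` matrices of recorded activations.
#' @param times sample times (s) of the recordings (uniform spacing).
#' @param pars a [balloon_parameters()].
#' @param baseline resting `f_e A_ee + (1-f_e) A_ei` (see [neural_drive()]).
#' @param output_dt output sampling interval (s); default 0.1 s.
#' @return list with `time`, `bold` (`n x length(time)`), final `state`.
#' @export
simulate_bold <- function(A_ee, A_ei, times, pars, baseline, output_dt = 0.1) {
  A_ee <- rbind(A_ee); A_ei <- rbind(A_ei)
  n <- nrow(A_ee)
  z <- neural_drive(A_ee, A_ei, pars, baseline)
  dt_in <- if (length(times) > 1) times[2] - times[1] else pars$dt_h
  t_end <- times[length(times)] + dt_in
  nh <- max(1L, floor(t_end / pars$dt_h))
  state <- matrix(rep(balloon_rest(pars), each = n), n, 4)
  out_every <- max(1L, round(output_dt / pars$dt_h))
  rec_t <- numeric(0); rec <- list()
  for (k in seq_len(nh)) {
    tt <- (k - 1) * pars$dt_h
    idx <- max(1L, min(ncol(z), findInterval(tt + 1e-12, times)))
    zi <- z[, idx]
    state <- balloon_step(state, zi, pars, pars$dt_h)
    if (k %% out_every == 0) {
      rec_t <- c(rec_t, tt + pars$dt_h)
      rec[[length(rec) + 1L]] <- bold_signal(state, pars)
    }
  }
  list(time = rec_t, bold = do.call(cbind, rec), state = state)
}
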