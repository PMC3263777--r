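#' Connectome with no connections
#'
#' Useful for isolated-vertex runs (fixed-point and decay checks).
#'
#' @param n number of vertices.
#' @return an empty `connectome`.
#' @export
empty_connectome <- function(n) {
  make_connectome(data.frame(src = integer(), dst = integer(),
                             weight = numeric(), delay_s = numeric(),
                             kind = character()), n, NULL)
}

#' Run the mesh NPM simulation
#'
#' Advances the delay-buffered two-population model with forward Euler at time
#' step `params$dt`, driving every vertex with independent Catmull-Rom
#' band-limited noise in the extracortical input `p_ee`. Long-range firing
#' rates travel through per-vertex delay ring buffers; connections whose delay
#' exceeds three transmission control-point spacings are splined (only control
#' points are exchanged and the receiving side reconstructs the rates).
#' Deterministic for a fixed seed. Results are independent of the partition
#' assignment by construction: deposits are always accumulated in a canonical
#' connection order, so a partitioned run exchanges the same control-point
#' streams and produces identical state.
#'
#' @param connectome a `connectome` (see [build_connectome()]), or
#'   [empty_connectome()] for isolated vertices.
#' @param params an [npm_parameters()] set.
#' @param duration simulated time (s).
#' @param seed RNG seed for the noise innovations.
#' @param init `"rest"` (start at the fixed point for the connectome's mean
#'   long-range gain) or a list with `h_e`, `h_i` (length n) and optional
#'   `I`, `J` (n x 4 matrices, pair order ee/ei/ie/ii).
#' @param observers character vector from `"mean_he"`, `"fields"` (per-vertex
#'   h_e, A_ee, A_ei at `record_every`), `"controls"` (transmitted spline
#'   control-point streams). Unknown observer names are an error at setup.
#' @param record_every decimation (steps) for per-vertex field recording.
#' @param mean_every decimation (steps) for the vertex-mean h_e/h_i series.
#' @param spline_transmission spline eligible long-range channels? Set FALSE
#'   to transmit every time step on every channel.
#' @param partitions optional integer vector (length n) assigning vertices to
#'   compute partitions; affects only the traffic accounting, not the result.
#' @param u_noise override the noise up-sampling factor (steps between noise
#'   control points); by default derived from `params$f_cut`. Used by
#'   [step_halving_check()] to feed the identical continuous noise input to
#'   runs at different time steps.
#' @return an `npm_simulation` object: vertex-mean series (`time_mean`,
#'   `mean_he`, `mean_hi`), optional per-vertex fields (`time_fields`, `h_e`,
#'   `A_ee`, `A_ei`), optional `controls`, final state, `params`, `n`, and
#'   `accounting` (transmitted value counts).
#' @export
run_simulation <- function(connectome, params, duration, seed,
                           init = "rest",
                           observers = c("mean_he", "fields"),
                           record_every = 100L, mean_every = 1L,
                           spline_transmission = TRUE,
                           partitions = NULL, u_noise = NULL) {
  allowed <- c("mean_he", "mean_hi", "fields", "controls")
  bad <- setdiff(observers, allowed)
  if (length(bad))
    stop("unknown observer(s): ", paste(bad, collapse = ", "),
         " (available: ", paste(allowed, collapse = ", "), ")")
  n <- connectome$n
  dt <- params$dt
  nsteps <- as.integer(round(duration / dt))
  if (nsteps < 1) stop("duration shorter than one time step")
  u_trans <- spline_upsampling(dt, params$f_cut_transmission)
  cc <- connectome$connections
  # canonical connection order: sorted by target then source (deterministic
  # regardless of construction or partitioning, and cache-friendly deposits)
  cc <- cc[order(cc$dst, cc$src, cc$delay_s), , drop = FALSE]
  delay_steps <- pmax(1L, discretize_delays(cc$delay_s, dt))
  splined <- spline_transmission & delay_steps > 3L * u_trans

  # noise control points (scaled innovations); zero when sd <= 0
  if (is.null(u_noise)) u_noise <- spline_upsampling(dt, params$f_cut)
  u_noise <- as.integer(u_noise)
  n_seg <- (nsteps - 1L) %/% u_noise + 1L
  if (params$p_ee_sd > 0) {
    set.seed(seed)
    ctrl <- noise_control_points(params$p_ee_sd, u_noise, nsteps, n)
  } else {
    ctrl <- matrix(0, n_seg + 3L, n)
  }

  state0 <- initial_state(init, connectome, params, n)
  core_pars <- build_core_pars(params)
  res <- .npm_core(n, nsteps, dt, core_pars,
                   as.integer(cc$src - 1L), as.integer(cc$dst - 1L),
                   as.numeric(cc$weight), delay_steps, splined,
                   u_trans, ctrl, u_noise, params$p_ee_mean,
                   state0$h_e, state0$h_i, state0$I, state0$J,
                   as.integer(record_every), as.integer(mean_every),
                   "fields" %in% observers, "controls" %in% observers)
  acct <- transmission_accounting(cc, delay_steps, splined, nsteps, u_trans,
                                  partitions)
  out <- list(time_mean = res$time_mean, mean_he = res$mean_he,
              mean_hi = res$mean_hi,
              time_fields = if ("fields" %in% observers) res$time_fields,
              h_e = if ("fields" %in% observers) res$h_e,
              A_ee = if ("fields" %in% observers) res$A_ee,
              A_ei = if ("fields" %in% observers) res$A_ei,
              controls = if ("controls" %in% observers) res$controls,
              final = list(h_e = res$he_final, h_i = res$hi_final,
                           I = res$I_final, J = res$J_final),
              n = n, dt = dt, duration = duration, seed = seed,
              u_trans = u_trans, params = params, accounting = acct)
  class(out) <- "npm_simulation"
  out
}

#' @export
print.npm_simulation <- function(x, ...) {
  cat(sprintf("npm_simulation: %d vertices, %.3g s at dt = %g s (seed %s)\n",
              x$n, x$duration, x$dt, format(x$seed)))
  cat(sprintf("  mean h_e over run: %.3f mV (sd %.4f)\n",
              mean(x$mean_he), stats::sd(x$mean_he)))
  invisible(x)
}

# resolve the initial state specification
initial_state <- function(init, connectome, params, n) {
  if (identical(init, "rest")) {
    cc <- connectome$connections
    gain <- if (nrow(cc)) mean(rowsum_safe(cc$weight, cc$dst, n)) else 0
    fp <- npm_fixed_point(params, long_range_gain = gain)
    list(h_e = rep(fp$h_e, n), h_i = rep(fp$h_i, n),
         I = matrix(rep(unname(fp$I), each = n), n, 4),
         J = matrix(0, n, 4))
  } else if (is.list(init)) {
    list(h_e = rep_len(init$h_e, n), h_i = rep_len(init$h_i, n),
         I = if (!is.null(init$I)) init$I else matrix(0, n, 4),
         J = if (!is.null(init$J)) init$J else matrix(0, n, 4))
  } else stop("'init' must be \"rest\" or a state list")
}

# flatten npm_parameters into the scalar/vector list the C++ core expects
build_core_pars <- function(params) {
  co <- psp_kernel_coefs(params$Q, params$delta, params$eps)
  list(tau_e = unname(params$tau["e"]), tau_i = unname(params$tau["i"]),
       h_rest_e = unname(params$h_rest["e"]), h_rest_i = unname(params$h_rest["i"]),
       S_max_e = unname(params$S_max["e"]), S_max_i = unname(params$S_max["i"]),
       mu_e = unname(params$mu["e"]), mu_i = unname(params$mu["i"]),
       sigma_e = unname(params$sigma["e"]), sigma_i = unname(params$sigma["i"]),
       h_eq = unname(params$h_eq),
       psi_den = unname(abs(params$h_eq - params$h_rest[c("e", "i", "e", "i")])),
       g1 = co$g1, g2 = co$g2, camp = co$camp,
       N_alpha = unname(params$N_alpha),
       Nb_ee = unname(params$N_beta["ee"]), Nb_ei = unname(params$N_beta["ei"]))
}

#' Transmitted-value accounting
#'
#' Counts the values each connection channel transmits over a run: one per
#' time step for per-step channels, one per `u` steps (the control points)
#' for splined channels. With a partition assignment, per-step counts are
#' aggregated per (source vertex, target partition) pair, mirroring the
#' compiled chunks a distributed run would exchange; within-partition traffic
#' is excluded.
#'
#' @param connections connectome connection table.
#' @param delay_steps integer delays (steps).
#' @param splined logical per connection.
#' @param nsteps run length (steps).
#' @param u transmission up-sampling factor.
#' @param partitions optional integer partition id per vertex.
#' @return list with `per_channel` counts, totals, and (with partitions) the
#'   cross-partition total.
#' @export
transmission_accounting <- function(connections, delay_steps, splined, nsteps,
                                    u, partitions = NULL) {
  n_events <- (nsteps - 1L) %/% u + 1L
  per_channel <- ifelse(splined, n_events, nsteps)
  out <- list(per_channel = per_channel,
              total = sum(per_channel),
              total_unsplined_equivalent = as.numeric(length(per_channel)) * nsteps)
  if (!is.null(partitions)) {
    src_part <- partitions[connections$src]
    dst_part <- partitions[connections$dst]
    cross <- src_part != dst_part
    # one stream per (source vertex, target partition); splined streams carry
    # control points only
    key <- paste(connections$src, dst_part, splined)
    first <- !duplicated(key) & cross
    out$cross_partition_total <- sum(ifelse(splined[first], n_events, nsteps))
  }
  out
}

#' Ring-buffer transmission primitives
#'
#' Small reference implementation of the per-vertex delay buffers used by the
#' integrator, exposed for inspection and property tests: [transmit_rates()]
#' deposits weighted source rates `delay` steps ahead of the current-time
#' pointer (modulo the buffer length); [consume_slot()] returns the
#' accumulated input at the current time and resets the slot.
#'
#' @param n number of vertices.
#' @param length buffer length (steps); must exceed the maximum delay.
#' @return `ring_buffer()`: a list with `slots` (n x length matrix) and the
#'   current-time pointer.
#' @export
ring_buffer <- function(n, length) {
  list(slots = matrix(0, n, length), ptr = 0L, length = as.integer(length))
}

#' @rdname ring_buffer
#' @param buffer a [ring_buffer()].
#' @param connections data.frame with `src`, `dst`, `weight` and integer
#'   `delay` (steps, in (0, buffer length)).
#' @param rates per-vertex source rates at the current time.
#' @export
transmit_rates <- function(buffer, connections, rates) {
  if (any(connections$delay >= buffer$length) || any(connections$delay < 1))
    stop("delay outside (0, buffer length) (buffer sizing bug)")
  for (k in seq_len(nrow(connections))) {
    slot <- (buffer$ptr + connections$delay[k]) %% buffer$length + 1L
    buffer$slots[connections$dst[k], slot] <-
      buffer$slots[connections$dst[k], slot] +
      connections$weight[k] * rates[connections$src[k]]
  }
  buffer
}

#' @rdname ring_buffer
#' @export
consume_slot <- function(buffer) {
  slot <- buffer$ptr %% buffer$length + 1L
  phi <- buffer$slots[, slot]
  buffer$slots[, slot] <- 0
  buffer$ptr <- buffer$ptr + 1L
  list(phi = phi, buffer = buffer)
}

#' Step-halving stability check
#'
#' Repeats a run with a five times smaller time step (and the same noise
#' control points) and compares the vertex-mean h_e trajectories at common
#' times.
#'
#' @param connectome,params,duration,seed as in [run_simulation()].
#' @param factor step reduction factor.
#' @return list with both simulations and the relative RMS difference of the
#'   common-time mean h_e series.
#' @export
step_halving_check <- function(connectome, params, duration, seed, factor = 5L) {
  u_c <- spline_upsampling(params$dt, params$f_cut)
  simA <- run_simulation(connectome, params, duration, seed,
                         observers = "mean_he", mean_every = 1L, u_noise = u_c)
  params2 <- params
  params2$dt <- params$dt / factor
  # same noise control points, interpolated at the finer step: the fine run
  # integrates the same continuous input
  simB <- run_simulation(connectome, params2, duration, seed,
                         observers = "mean_he", mean_every = as.integer(factor),
                         u_noise = u_c * factor)
  nn <- min(length(simA$mean_he), length(simB$mean_he))
  a <- simA$mean_he[seq_len(nn)]; b <- simB$mean_he[seq_len(nn)]
  list(coarse = simA, fine = simB,
       rms_rel = sqrt(mean((a - b)^2)) / stats::sd(a))
}
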