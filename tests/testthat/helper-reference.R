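# Independent explicit-history reference for the delay-buffered integrator:
# stores complete rate histories and computes every delayed input directly as
# sum_b w * s(t - delay), with Catmull-Rom reconstruction from the control
# sequence for splined channels. No ring buffers. Usable only at small n.
reference_simulation <- function(connectome, params, duration, seed,
                                 init = "rest", spline_transmission = TRUE,
                                 u_noise = NULL) {
  n <- connectome$n
  dt <- params$dt
  nsteps <- as.integer(round(duration / dt))
  u <- spline_upsampling(dt, params$f_cut_transmission)
  cc <- connectome$connections
  delay <- pmax(1L, as.integer(round(cc$delay_s / dt)))
  splined <- spline_transmission & delay > 3L * u

  if (is.null(u_noise)) u_noise <- spline_upsampling(dt, params$f_cut)
  if (params$p_ee_sd > 0) {
    set.seed(seed)
    ctrl <- noise_control_points(params$p_ee_sd, u_noise, nsteps, n)
  } else {
    ctrl <- matrix(0, (nsteps - 1L) %/% u_noise + 4L, n)
  }

  if (identical(init, "rest")) {
    gain <- if (nrow(cc)) mean(rowsum_safe(cc$weight, cc$dst, n)) else 0
    fp <- npm_fixed_point(params, long_range_gain = gain)
    h_e <- rep(fp$h_e, n); h_i <- rep(fp$h_i, n)
    I <- matrix(rep(unname(fp$I), each = n), n, 4)
    J <- matrix(0, n, 4)
  } else {
    h_e <- rep_len(init$h_e, n); h_i <- rep_len(init$h_i, n)
    I <- if (!is.null(init$I)) init$I else matrix(0, n, 4)
    J <- if (!is.null(init$J)) init$J else matrix(0, n, 4)
  }

  co <- psp_kernel_coefs(params$Q, params$delta, params$eps)
  psi_den <- abs(params$h_eq - params$h_rest[c("e", "i", "e", "i")])
  Smax_e <- params$S_max["e"]; Smax_i <- params$S_max["i"]
  mu_e <- params$mu["e"]; mu_i <- params$mu["i"]
  sg_e <- params$sigma["e"]; sg_i <- params$sigma["i"]

  s0 <- sigmoid_rate(h_e, Smax_e, mu_e, sg_e)
  Shist <- matrix(0, n, nsteps)          # complete e-rate history
  n_ctrl <- nsteps %/% u + 3L
  Chist <- matrix(0, n, n_ctrl)          # control points c_0, c_1, ...

  he_rec <- matrix(0, n, nsteps)
  phi_of_t <- function(t, se_now) {      # t is 0-based step index
    phi <- numeric(n)
    if (!nrow(cc)) return(phi)
    td <- t - delay
    vals <- numeric(nrow(cc))
    uns <- which(!splined)
    if (length(uns)) {
      tdu <- td[uns]
      v <- ifelse(tdu < 0, s0[cc$src[uns]],
                  Shist[cbind(cc$src[uns], pmax(tdu, 0) + 1L)])
      vals[uns] <- v
    }
    sp <- which(splined)
    if (length(sp)) {
      tds <- td[sp]
      m <- tds %/% u
      x <- (tds %% u) / u
      w <- catmull_rom_weights(x)
      acc <- numeric(length(sp))
      for (k in 1:4) {
        cidx <- m + (k - 2L)             # control index (c_0 at column 1)
        v <- ifelse(cidx < 0, s0[cc$src[sp]],
                    Chist[cbind(cc$src[sp], pmax(cidx, 0) + 1L)])
        acc <- acc + w[, k] * v
      }
      vals[sp] <- acc
    }
    rowsum_safe(cc$weight * vals, cc$dst, n)
  }

  for (t in 0:(nsteps - 1L)) {
    se <- Smax_e / (1 + exp(-sqrt(2) * (h_e - mu_e) / sg_e))
    si <- Smax_i / (1 + exp(-sqrt(2) * (h_i - mu_i) / sg_i))
    Shist[, t + 1L] <- se
    if (t %% u == 0L) Chist[, t %/% u + 1L] <- se
    phi <- phi_of_t(t, se)
    m <- t %/% u_noise
    x <- (t %% u_noise) / u_noise
    w <- catmull_rom_weights(x)
    pnoise <- params$p_ee_mean +
      (w[1] * ctrl[m + 1L, ] + w[2] * ctrl[m + 2L, ] +
       w[3] * ctrl[m + 3L, ] + w[4] * ctrl[m + 4L, ])
    A <- cbind(params$N_alpha["ee"] * se + pnoise + params$N_beta["ee"] * phi,
               params$N_alpha["ei"] * se + params$N_beta["ei"] * phi,
               params$N_alpha["ie"] * si,
               params$N_alpha["ii"] * si)
    he_rec[, t + 1L] <- h_e
    h_e_new <- h_e + dt * ((params$h_rest["e"] - h_e +
                 (params$h_eq["ee"] - h_e) / psi_den["ee"] * I[, 1] +
                 (params$h_eq["ie"] - h_e) / psi_den["ie"] * I[, 3]) / params$tau["e"])
    h_i_new <- h_i + dt * ((params$h_rest["i"] - h_i +
                 (params$h_eq["ei"] - h_i) / psi_den["ei"] * I[, 2] +
                 (params$h_eq["ii"] - h_i) / psi_den["ii"] * I[, 4]) / params$tau["i"])
    I_new <- I + dt * J
    J <- J + dt * (-sweep(J, 2, co$g1 + co$g2, "*") -
                   sweep(I, 2, co$g1 * co$g2, "*") +
                   sweep(A, 2, co$camp, "*"))
    I <- I_new; h_e <- h_e_new; h_i <- h_i_new
  }
  list(h_e_hist = he_rec, mean_he = colMeans(he_rec),
       final = list(h_e = h_e, h_i = h_i, I = I, J = J))
}

# small connected fixture connectome on n vertices with assorted delays
toy_connectome <- function(n, dt, u, seed = 42, include_splined = TRUE) {
  set.seed(seed)
  dst <- rep(seq_len(n), each = 3)        # every vertex receives 3 channels
  src <- as.vector(vapply(seq_len(n),
                          function(i) sample(setdiff(seq_len(n), i), 3), integer(3)))
  w <- stats::runif(length(src), 0.1, 1)
  tot <- rowsum_safe(w, dst, n)
  w <- w / tot[dst]                       # background-style: sums to 1 per target
  # delays: mix short (per-step) and long (splineable) channels
  steps <- sample(c(2:(3 * u), (3 * u + 1):(8 * u)), length(src), replace = TRUE)
  if (!include_splined) steps <- sample(2:(3 * u), length(src), replace = TRUE)
  make_connectome(data.frame(src = src, dst = dst, weight = w,
                             delay_s = steps * dt, kind = "background"),
                  n, NULL)
}
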