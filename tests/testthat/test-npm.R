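test_that("sigmoid rate has midpoint, saturation and monotonicity", {
  expect_equal(sigmoid_rate(-50, 500, -50, 5), 250)
  expect_equal(sigmoid_rate(1e4, 500, -50, 5), 500)
  expect_equal(sigmoid_rate(-1e4, 500, -50, 5), 0)
  h <- seq(-100, 0, length.out = 1000)
  expect_true(all(diff(sigmoid_rate(h, 500, -50, 5)) > 0))
  expect_true(all(sigmoid_rate(h, 500, -50, 5) > 0))
})

test_that("alpha PSP: zero at 0, peak Q at delta, flat at the peak", {
  Q <- 0.71; delta <- 1 / 300
  expect_equal(psp_impulse_response(Q, delta, 0, 0), 0)
  expect_equal(psp_impulse_response(Q, delta, 0, delta), Q)
  de <- 1e-7
  slope <- (psp_impulse_response(Q, delta, 0, delta + de) -
            psp_impulse_response(Q, delta, 0, delta - de)) / (2 * de)
  expect_lt(abs(slope), 1e-3 * Q / delta)
  expect_error(psp_impulse_response(Q, -1, 0, 0.1), "delta")
})

test_that("bi-exponential PSP is continuous in eps, keeps peak Q, decays slower", {
  Q <- 1; delta <- 0.005
  t <- seq(0, 0.1, by = 1e-5)
  a0 <- psp_impulse_response(Q, delta, 0, t)
  a1 <- psp_impulse_response(Q, delta, 1e-6, t)
  expect_lt(max(abs(a0 - a1)), 1e-4)
  a2 <- psp_impulse_response(Q, delta, 0.8, t)
  expect_equal(max(a2), Q, tolerance = 1e-6)
  expect_gt(sum(a2), sum(a0))  # prolonged decay carries more area
})

test_that("the PSP ODE integrator reproduces the closed-form kernel", {
  # drive the second-order kernel with a discrete delta at the default step
  p <- npm_parameters()
  co <- meshnpm:::psp_kernel_coefs(p$Q, p$delta, p$eps)
  dt <- p$dt
  # first-order Euler error scales with dt/delta: ~1% for the fast excitatory
  # kernel (delta = 3.3 ms), well under 0.5% for the slow inhibitory one
  tol <- c(0.01, NA, 0.005, NA)
  for (pair in c(1, 3)) {
    nst <- 3000
    # a Dirac input is the initial condition I = 0, I' = camp
    I <- 0; J <- co$camp[pair]
    out <- numeric(nst)
    for (s in seq_len(nst)) {
      out[s] <- I
      Inew <- I + dt * J
      J <- J + dt * (-(co$g1[pair] + co$g2[pair]) * J - co$g1[pair] * co$g2[pair] * I)
      I <- Inew
    }
    tt <- (seq_len(nst) - 1) * dt
    exact <- psp_impulse_response(p$Q[pair], p$delta[pair], 0, tt)
    expect_lt(max(abs(out - exact)) / max(exact), tol[pair])
  }
})

test_that("input-free membrane potentials decay with their time constants", {
  p <- npm_parameters(p_ee_sd = 0)
  p$N_alpha[] <- 0; p$N_beta[] <- 0; p$p_ee_mean <- 0
  sim <- run_simulation(empty_connectome(1), p, duration = 0.5, seed = 1,
                        init = list(h_e = -60, h_i = -62), observers = "mean_he")
  tt <- sim$time_mean
  fit_e <- stats::lm(log(sim$mean_he + 70) ~ tt)
  expect_lt(abs(-1 / coef(fit_e)[2] - p$tau["e"]) / p$tau["e"], 0.01)
  fit_i <- stats::lm(log(sim$mean_hi + 70) ~ tt)
  expect_lt(abs(-1 / coef(fit_i)[2] - p$tau["i"]) / p$tau["i"], 0.01)
})

test_that("a 10 s noise-free run converges to the independent Newton fixed point", {
  p <- npm_parameters(p_ee_sd = 0)
  fp <- npm_fixed_point(p, long_range_gain = 0)
  expect_lt(max(abs(fp$residual)), 1e-10)
  sim <- run_simulation(empty_connectome(1), p, duration = 10, seed = 1,
                        init = list(h_e = -62, h_i = -75), observers = "mean_he")
  expect_lt(abs(sim$final$h_e - fp$h_e), 0.01)
  expect_lt(abs(sim$final$h_i - fp$h_i), 0.01)
})

test_that("zero noise starting at the fixed point stays constant", {
  p <- npm_parameters(p_ee_sd = 0)
  u <- spline_upsampling(p$dt, p$f_cut_transmission)
  cn <- toy_connectome(8, p$dt, u, seed = 3)
  sim <- run_simulation(cn, p, duration = 0.2, seed = 1, observers = "mean_he")
  expect_lt(diff(range(sim$mean_he)), 1e-8)
})

test_that("buffered delayed transmission equals the explicit-history reference", {
  p <- npm_parameters()
  u <- spline_upsampling(p$dt, p$f_cut_transmission)
  cn <- toy_connectome(20, p$dt, u, seed = 42)
  # unsplined: every channel transmits every step
  simc <- run_simulation(cn, p, duration = 0.4, seed = 7, observers = "fields",
                         record_every = 1L, spline_transmission = FALSE)
  ref <- reference_simulation(cn, p, duration = 0.4, seed = 7,
                              spline_transmission = FALSE)
  expect_lte(max(abs(simc$h_e - ref$h_e_hist)), 1e-10)
  # splined deposit-side reconstruction equals consumption-side interpolation
  sims <- run_simulation(cn, p, duration = 0.4, seed = 7, observers = "fields",
                         record_every = 1L, spline_transmission = TRUE)
  refs <- reference_simulation(cn, p, duration = 0.4, seed = 7,
                               spline_transmission = TRUE)
  expect_lte(max(abs(sims$h_e - refs$h_e_hist)), 1e-10)
  # splined vs raw-history transmission: within 1% of the signal scale
  expect_lt(max(abs(sims$h_e - ref$h_e_hist)),
            0.01 * max(stats::sd(ref$h_e_hist), 1e-3))
})

test_that("constant source rates converge to the summed weighted input", {
  # at the noise-free fixed point, the consumed long-range input phi equals
  # total_weight * s_e, so A_ee = N_alpha s_e + p + N_beta * gain * s_e
  p <- npm_parameters(p_ee_sd = 0)
  u <- spline_upsampling(p$dt, p$f_cut_transmission)
  cn <- toy_connectome(8, p$dt, u, seed = 3)
  gain <- mean(rowsum_ref(cn$connections$weight, cn$connections$dst, 8))
  expect_equal(gain, 1, tolerance = 1e-12)   # background-style normalization
  fp <- npm_fixed_point(p, long_range_gain = 1)
  sim <- run_simulation(cn, p, duration = 0.3, seed = 1, observers = "fields",
                        record_every = 10L)
  nt <- ncol(sim$A_ee)
  A_ee_expect <- p$N_alpha["ee"] * fp$s_e + p$p_ee_mean + p$N_beta["ee"] * fp$s_e
  expect_equal(unname(sim$A_ee[, nt]), rep(unname(A_ee_expect), 8),
               tolerance = 1e-8)
})

test_that("simulations are deterministic and partition-independent", {
  p <- npm_parameters()
  u <- spline_upsampling(p$dt, p$f_cut_transmission)
  cn <- toy_connectome(20, p$dt, u, seed = 42)
  s1 <- run_simulation(cn, p, duration = 0.2, seed = 5,
                       observers = c("mean_he", "fields", "controls"),
                       record_every = 10L)
  s2 <- run_simulation(cn, p, duration = 0.2, seed = 5,
                       observers = c("mean_he", "fields", "controls"),
                       record_every = 10L)
  expect_identical(s1$mean_he, s2$mean_he)
  part <- rep(1:2, each = 10)
  s3 <- run_simulation(cn, p, duration = 0.2, seed = 5,
                       observers = c("mean_he", "fields", "controls"),
                       record_every = 10L, partitions = part)
  # bitwise-identical control-point streams and state
  expect_identical(s3$controls, s1$controls)
  expect_lte(max(abs(s3$h_e - s1$h_e)), 1e-10)
  expect_true(s3$accounting$cross_partition_total <
              s3$accounting$total_unsplined_equivalent)
})

test_that("unknown observers fail at setup time", {
  p <- npm_parameters()
  expect_error(run_simulation(empty_connectome(2), p, 0.01, 1,
                              observers = "h_i_gradient"), "unknown observer")
})

test_that("ring-buffer transmission conserves deposited weight", {
  set.seed(1)
  conn <- data.frame(src = c(1, 1, 2, 3), dst = c(2, 3, 1, 1),
                     weight = runif(4), delay = c(2L, 5L, 3L, 7L))
  buf <- ring_buffer(3, 8)
  rates <- c(1, 1, 1)                      # one unit "spike" per source
  buf <- transmit_rates(buf, conn, rates)
  expect_equal(sum(buf$slots), sum(conn$weight))   # nothing lost at wrap-around
  total <- 0
  for (k in 1:8) {
    out <- consume_slot(buf)
    buf <- out$buffer
    total <- total + sum(out$phi)
  }
  expect_equal(total, sum(conn$weight))
  expect_equal(sum(buf$slots), 0)
  expect_error(transmit_rates(ring_buffer(3, 4), conn, rates), "buffer sizing")
})

test_that("splined channels transmit exactly u-fold fewer values", {
  p <- npm_parameters()
  u <- spline_upsampling(p$dt, p$f_cut_transmission)
  cn <- toy_connectome(10, p$dt, u, seed = 8)
  steps <- pmax(1L, discretize_delays(cn$connections$delay_s, p$dt))
  splined <- steps > 3L * u
  nsteps <- 1000L
  acct <- transmission_accounting(cn$connections, steps, splined, nsteps, u)
  expect_true(any(splined) && any(!splined))
  expect_equal(unique(acct$per_channel[!splined] / acct$per_channel[splined]),
               u)
})

test_that("halving the time step five-fold changes trajectories by < 2% RMS", {
  p <- npm_parameters()
  u <- spline_upsampling(p$dt, p$f_cut_transmission)
  cn <- toy_connectome(8, p$dt, u, seed = 3)
  chk <- step_halving_check(cn, p, duration = 0.6, seed = 4)
  expect_lt(chk$rms_rel, 0.02)
})

test_that("the exported single step matches the compiled integrator exactly", {
  p <- npm_parameters(p_ee_sd = 0)
  sim <- run_simulation(empty_connectome(3), p, duration = p$dt * 10, seed = 1,
                        init = list(h_e = c(-60, -70, -80), h_i = -65),
                        observers = "fields", record_every = 1L)
  st <- list(h_e = c(-60, -70, -80), h_i = rep(-65, 3),
             I = matrix(0, 3, 4), J = matrix(0, 3, 4))
  for (k in 1:9) st <- step_state(st, p, phi = 0)$state
  expect_equal(st$h_e, sim$h_e[, 10], tolerance = 1e-14)
  expect_error(step_state(list(h_e = NaN, h_i = -65, I = matrix(0, 1, 4),
                               J = matrix(0, 1, 4)), p), "non-finite")
})
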