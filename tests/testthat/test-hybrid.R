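test_that("emulated K current is zero at E_K for all scales and states", {
  for (s in list(s_nbox, scaling_factors(1, 1, 1), scaling_factors(5, 0.2, 40))) {
    for (w in c(nbox$w_min, 0.5, nbox$w_max))
      expect_equal(memristor_k_current(nbox, s, w, -77, -77), 0)
  }
})

test_that("identity scales reduce the emulated current to the device law", {
  sI <- scaling_factors(1, 1, 1)
  v <- c(-80, -70, -60, -40)
  expect_equal(memristor_k_current(nbox, sI, 0.3, v, -77),
               device_current(nbox, 0.3, v - -77))
})

test_that("emulated K current composes scaling and device law", {
  # w = w_min, v = -60, E_K = -77: device bias 0.11 * 17 volts
  got <- memristor_k_current(nbox, s_nbox, nbox$w_min, -60, -77)
  expect_equal(got, s_nbox$I_scale *
                 ref_device_current(nbox, nbox$w_min, 0.11 * 17))
})

test_that("emulated state rate scales linearly with T_scale", {
  expect_equal(memristor_k_rate(nbox, s_nbox, nbox$w_min, -77, -77), 0)
  s2 <- scaling_factors(s_nbox$V_scale, 2 * s_nbox$T_scale, s_nbox$I_scale)
  expect_equal(memristor_k_rate(nbox, s2, 0.3, -20, -77),
               2 * memristor_k_rate(nbox, s_nbox, 0.3, -20, -77))
  expect_equal(memristor_k_rate(nbox, s_nbox, 0.3, -20, -77),
               s_nbox$T_scale *
                 ref_state_rate(nbox, 0.3, s_nbox$V_scale * (-20 - -77)))
})

test_that("hybrid neuron is quiescent without stimulus", {
  tr <- simulate_hybrid(hh0, nbox, s_nbox, const_stim(0, 200))
  expect_length(detect_spikes(tr)$times_ms, 0)
  # settles to a subthreshold equilibrium
  expect_lt(diff(range(tail(tr$V_mV, 1000))), 0.01)
})

test_that("state bounds hold throughout a noisy hybrid simulation", {
  tr <- simulate_hybrid(hh0, nbox, s_nbox, ou_process(200, seed = 4))
  expect_true(all(tr$w >= nbox$w_min & tr$w <= nbox$w_max))
  expect_true(all(tr$m >= 0 & tr$m <= 1 & tr$h >= 0 & tr$h <= 1))
})

test_that("linear device law restores spike height relative to sinh law", {
  stim <- ou_process(400, seed = 6)
  hs <- simulate_hybrid(hh0, nbox, s_nbox, stim, law = "sinh")
  hl <- simulate_hybrid(hh0, nbox, s_nbox, stim, law = "linear")
  ps <- detect_spikes(hs)$peaks_mV
  pl <- detect_spikes(hl)$peaks_mV
  expect_gt(length(ps), 0)
  expect_gt(length(pl), 0)
  expect_gt(mean(pl), mean(ps))
})

test_that("physically scaled circuit reproduces the unit-space equations", {
  s <- scaling_factors(0.11, 1.26, 1.91)
  dt <- 0.005
  stim <- ou_process(25, dt = dt, seed = 9)
  hy <- simulate_hybrid(hh0, nbox, s, stim, dt)
  pc <- scale_passive(hh0, s)
  dtp <- dt * s$T_scale
  g <- gate_steady(-60)
  Vp <- s$V_scale * -60; m <- g$m_inf; h <- g$h_inf; w <- nbox$w_min
  iapp <- stim$i_app
  vrec <- numeric(length(iapp))
  for (k in seq_along(iapp)) {
    vrec[k] <- Vp
    r <- gate_rates(Vp / s$V_scale)
    idev <- device_current(nbox, w, Vp - pc$E_K)
    iNa <- pc$g_Na * m^3 * h * (Vp - pc$E_Na)
    iL <- (Vp - pc$E_L) / pc$R_L
    dw <- state_rate(nbox, w, Vp - pc$E_K)
    Vp <- Vp + dtp * (iapp[k] / s$I_scale - iNa - idev - iL) / pc$C_m
    m <- min(1, max(0, m + dtp * (r$alpha_m * (1 - m) - r$beta_m * m) / s$T_scale))
    h <- min(1, max(0, h + dtp * (r$alpha_h * (1 - h) - r$beta_h * h) / s$T_scale))
    w <- min(nbox$w_max, max(nbox$w_min, w + dtp * dw))
  }
  err <- max(abs(vrec / s$V_scale - hy$V_mV)) / diff(range(hy$V_mV))
  expect_lt(err, 1e-9)
})

test_that("identity scales leave passive components unchanged", {
  pc <- scale_passive(hh0, scaling_factors(1, 1, 1))
  expect_equal(pc$E_K, hh0$E_K)
  expect_equal(pc$C_m, hh0$C_m)
  expect_equal(pc$R_L, 1 / hh0$g_L)
})

test_that("reversal potentials scale to physical volts", {
  pc <- scale_passive(hh0, scaling_factors(0.11, 1.26, 1.91))
  expect_equal(pc$E_K, -8.47)
})

test_that("steady-state comparison is zero at E_K and surges under sinh", {
  tab <- steady_state_comparison(hh0, nbox, s_nbox, v = seq(-90, 20, by = 1))
  at_rev <- tab[tab$v == hh0$E_K, ]
  expect_equal(at_rev$i_K_hh, 0)
  expect_equal(at_rev$i_K_mem, 0)
  # pointwise oracle
  v0 <- -50
  winf <- steady_state_w(nbox, s_nbox$V_scale * (v0 - hh0$E_K))
  expect_equal(tab$i_K_mem[tab$v == v0],
               s_nbox$I_scale * ref_device_current(nbox, winf,
                                                   s_nbox$V_scale * (v0 + 77)))
  # super-linear growth of the memristor branch at large depolarisation
  i20 <- tab$i_K_mem[tab$v == 0]
  i10 <- tab$i_K_mem[tab$v == -20]
  expect_gt(i20 / i10, (0 + 77) / (-20 + 77) * 2)
})
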