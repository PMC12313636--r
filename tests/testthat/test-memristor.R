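test_that("device current matches the Schottky + tunneling law", {
  # frozen from independent arithmetic: (1-0.117)*0.0271*(1-exp(-0.503*0.7))
  #   + 0.117*11.138*sinh(0.739*0.7)
  expect_equal(device_current(nbox, 0.117, 0.7), 0.7116898, tolerance = 1e-6)
  expect_equal(device_current(nbox, 0.5, 0), 0)
  # every zero-bias current is pinched, any state
  for (w in seq(nbox$w_min, nbox$w_max, length.out = 7))
    expect_identical(device_current(nbox, w, 0), 0)
  # odd-sign structure: i(-V) < 0 where i(V) > 0
  iplus <- device_current(nbox, nbox$w_min, 0.8)
  iminus <- device_current(nbox, nbox$w_min, -0.8)
  expect_gt(iplus, 0)
  expect_lt(iminus, 0)
})

test_that("device current carries the sign of the bias for any state", {
  for (p in list(nbox, wox)) {
    for (w in seq(p$w_min, p$w_max, length.out = 5)) {
      V <- c(-2, -0.5, -0.01, 0.01, 0.5, 2)
      expect_equal(sign(device_current(p, w, V)), sign(V))
    }
  }
})

test_that("device current agrees with reference arithmetic on a grid", {
  set.seed(42)
  for (k in 1:20) {
    w <- runif(1, nbox$w_min, nbox$w_max)
    V <- runif(1, -3, 3)
    expect_equal(device_current(nbox, w, V), ref_device_current(nbox, w, V))
  }
})

test_that("out-of-bounds state is rejected", {
  expect_error(device_current(nbox, 1.5, 0.5), "out of bounds")
  expect_error(state_rate(nbox, 0.05, 0.5), "out of bounds")
})

test_that("window function is 1 - exp(w - 3), decreasing, zero at w = 3", {
  expect_equal(memristor_window(3), 0)
  expect_equal(memristor_window(0.117), 0.9440334, tolerance = 1e-6)
  expect_equal(memristor_window(0.99), 0.8660113, tolerance = 1e-6)
  w <- seq(0, 1, by = 0.1)
  expect_true(all(diff(memristor_window(w)) < 0))
})

test_that("state dynamics balance potentiation and decay", {
  expect_equal(state_rate(nbox, nbox$w_min, 0), 0)
  expect_gt(state_rate(nbox, nbox$w_min, 0.5), 0)
  # decay term alone: -(0.3 - 0.117)/11.7
  expect_equal(state_rate(nbox, 0.3, 0), -(0.3 - 0.117) / 11.7)
  set.seed(1)
  for (k in 1:10) {
    w <- runif(1, nbox$w_min, nbox$w_max)
    V <- runif(1, -2, 2)
    expect_equal(state_rate(nbox, w, V), ref_state_rate(nbox, w, V))
  }
})

test_that("one Euler step follows the rate and respects the clip", {
  expect_equal(step_state(nbox, nbox$w_min, 0, 0.005), nbox$w_min)
  # hand-computed single step at the write voltage
  rate <- (1 - exp(0.117 - 3)) * 0.0155 * sinh(0.739 * 4)
  expect_equal(step_state(nbox, 0.117, 4, 0.005), 0.117 + 0.005 * rate)
  # a huge drive cannot push past w_max
  expect_equal(step_state(nbox, 0.98, 40, 1), nbox$w_max)
  expect_error(step_state(nbox, 0.5, 1, 0), "dt")
})

test_that("state stays confined for arbitrary stimulus sequences", {
  set.seed(7)
  for (rep in 1:5) {
    V <- runif(2000, -5, 5)
    sim <- memhh:::cpp_device_sim(memhh:::.mp_vec(nbox), V, nbox$w_min, 0.01)
    expect_true(all(sim$w >= nbox$w_min & sim$w <= nbox$w_max))
  }
})

test_that("steady state is w_min at rest, sigmoidal and saturating in V", {
  expect_equal(steady_state_w(nbox, 0), nbox$w_min)
  expect_equal(steady_state_w(nbox, 1), 0.2635534, tolerance = 1e-6)
  Vsat <- asinh(nbox$w_max / (nbox$tau * nbox$lam)) / nbox$eta
  expect_equal(steady_state_w(nbox, Vsat + 0.01), nbox$w_max)
  V <- seq(0, 8, by = 0.05)
  expect_true(all(diff(steady_state_w(nbox, V)) >= 0))
})

test_that("effective time constant switches from tau to drive-limited", {
  expect_equal(effective_time_constant(nbox, 0), nbox$tau)
  # V where tau*lam*sinh(eta V) = 10 gives tau/10
  V10 <- asinh(10 / (nbox$tau * nbox$lam)) / nbox$eta
  expect_equal(effective_time_constant(nbox, V10), nbox$tau / 10,
               tolerance = 1e-10)
  # strong-drive branch never exceeds tau
  V <- seq(0, 8, by = 0.1)
  expect_true(all(effective_time_constant(nbox, V) <= nbox$tau + 1e-12))
  # branch predicate can differ between devices at the same bias
  drive <- function(p, V) p$tau * p$lam * sinh(p$eta * V)
  expect_lt(drive(nbox, 0.5), 1)
  expect_gt(drive(wox, 0.5), 1)
})

test_that("linearization is first order with a Schottky leak term", {
  expect_equal(linearized_current(nbox, 0.5, 0), 0)
  expect_equal(
    linearized_current(nbox, 0.5, 0.01),
    0.5 * (11.138 * 0.739 - 0.0271 * 0.503) * 0.01 + 0.0271 * 0.503 * 0.01)
  # quadratic residual: |i - lin| <= C V^2 on |V| <= 0.05 with C stable
  w <- 0.4
  V <- seq(-0.05, 0.05, by = 0.002); V <- V[V != 0]
  resid <- abs(device_current(nbox, w, V) - linearized_current(nbox, w, V))
  C <- max(resid / V^2)
  Vs <- V / 2
  resid2 <- abs(device_current(nbox, w, Vs) - linearized_current(nbox, w, Vs))
  expect_true(all(resid2 <= C * Vs^2 + 1e-12))
})

test_that("linear variant has state-linear, bias-independent conductance", {
  expect_equal(linear_variant_current(nbox, 0.5, 0), 0)
  g1 <- linear_variant_current(nbox, 0.5, 0.3) / 0.3
  g2 <- linear_variant_current(nbox, 0.5, 1.7) / 1.7
  expect_equal(g1, g2)
})

test_that("sinusoidal drive yields a pinched hysteresis loop", {
  expect_identical(hysteresis_trace(nbox, 0, freq = 0.05)$i_uA,
                   rep(0, nrow(hysteresis_trace(nbox, 0, freq = 0.05))))
  # drive period comparable to tau; pinched at origin and finite loop area
  tr <- hysteresis_trace(nbox, 2, freq = 1 / nbox$tau, dt = 0.005, cycles = 3)
  expect_true(all(abs(tr$i_uA[abs(tr$V_volts) < 1e-12]) < 1e-12))
  # signed loop area per cycle by trapezoidal contour integral of i dV
  dV <- diff(tr$V_volts)
  area <- abs(sum((tr$i_uA[-1] + tr$i_uA[-nrow(tr)]) / 2 * dV))
  expect_gt(area, 0.01)
})

test_that("halving dt changes a 100-ms device trajectory endpoint by < 1%", {
  t1 <- seq(0, 100, by = 0.01)[-1]
  V1 <- 2 * abs(sin(2 * pi * t1 / 40))
  s1 <- memhh:::cpp_device_sim(memhh:::.mp_vec(nbox), V1, nbox$w_min, 0.01)
  t2 <- seq(0, 100, by = 0.005)[-1]
  V2 <- 2 * abs(sin(2 * pi * t2 / 40))
  s2 <- memhh:::cpp_device_sim(memhh:::.mp_vec(nbox), V2, nbox$w_min, 0.005)
  w1 <- s1$w[length(s1$w)]; w2 <- s2$w[length(s2$w)]
  expect_lt(abs(w1 - w2) / w2, 0.01)
})

test_that("unphysical biases are clamped with a warning", {
  expect_warning(device_current(nbox, 0.5, 80), "clamped")
})

test_that("parameter constructors validate their invariants", {
  expect_error(memristor_params(-1, 1, 1, 1, 1, 1, 1, 0.1), "tau")
  expect_error(memristor_params(1, -1, 1, 1, 1, 1, 1, 0.1), ">= 0")
  expect_error(memristor_params(1, 1, 1, 1, 1, 1, 1, 0), "bounds")
  expect_error(memristor_params(1, 1, 1, 1, 1, 1, 1, 0.5, w_max = 1.5),
               "bounds")
  p <- device_preset("wox")
  expect_s3_class(p, "memristor_params")
  expect_equal(p$tau, 50)
})
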