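truth_reduced <- reduced_params(tau = 11.7, A = 1.28, G_min = 2.18)
small_proto <- pulse_protocol(noise_sd = 0, replicate = 3)

test_that("reduced fit recovers tau, A, G_min from noiseless data", {
  d <- generate_potentiation_decay(truth_reduced, small_proto, seed = 1)
  f <- fit_reduced(d$G, d$V, steps = 2500, optimizer = "adam")
  cf <- coef(f)
  expect_lt(abs(cf[["tau"]] / 11.7 - 1), 0.05)
  expect_lt(abs(cf[["A"]] / 1.28 - 1), 0.05)
  expect_lt(abs(cf[["G_min"]] / 2.18 - 1), 0.05)
  expect_s3_class(f, "memfit")
  expect_equal(length(fitted(f)), length(d$G$G_uS))
  expect_lt(max(abs(residuals(f))), 0.05)
})

test_that("reduced fit tolerates 1% measurement noise", {
  proto <- pulse_protocol(noise_sd = 0.01, replicate = 3)
  d <- generate_potentiation_decay(truth_reduced, proto, seed = 2)
  f <- fit_reduced(d$G, d$V, optimizer = "lbfgs")
  expect_lt(abs(coef(f)[["tau"]] / 11.7 - 1), 0.10)
  expect_lt(abs(coef(f)[["A"]] / 1.28 - 1), 0.10)
  expect_lt(abs(coef(f)[["G_min"]] / 2.18 - 1), 0.10)
})

test_that("tau recovery is robust across noise realizations", {
  errs <- vapply(1:20, function(seed) {
    proto <- pulse_protocol(noise_sd = 0.01, replicate = 2)
    d <- generate_potentiation_decay(truth_reduced, proto, seed = seed)
    f <- fit_reduced(d$G, d$V, optimizer = "lbfgs")
    abs(coef(f)[["tau"]] / 11.7 - 1)
  }, numeric(1))
  expect_lt(median(errs), 0.05)
})

test_that("degenerate flat data does not break the reduced fit", {
  G <- rep(2.18, 5000)
  V <- rep(0, 5000)
  f <- fit_reduced(G, V, dt = 0.05, optimizer = "lbfgs")
  expect_true(all(is.finite(coef(f))))
  expect_lt(coef(f)[["A"]] * 10, 2.18)  # potentiation rate effectively zero
  expect_lt(f$loss, 1e-8)
})

test_that("constraint loss evaluates the published penalty table", {
  ok <- list(alpha = 1, beta = 0.5, gamma = 1, delta = 1, eta = 1,
             lam = 0.01, w_min = 0.15)
  expect_equal(as.numeric(constraint_loss(ok, w_trajectory = c(0.2, 0.9))), 0)
  # a negative alpha costs 1e4 * |alpha|
  bad <- ok; bad$alpha <- -0.1
  expect_equal(as.numeric(constraint_loss(bad)), 1e4 * 0.1)
  # trajectory overshoot: sum of w above 1, weight 1e2
  expect_equal(as.numeric(constraint_loss(ok, w_trajectory = c(0.5, 1.2))),
               1e2 * 1.2)
  # fitted NbOx values leave only the two anchor residuals
  fitted_nbox <- as.list(device_preset("nbox"))
  got <- constraint_loss(fitted_nbox, w_trajectory = c(0.117, 0.5))
  expect_equal(as.numeric(got),
               1e3 * (0.117 - 0.15)^2 + (0.503 - 0.5)^2)
  terms <- attr(got, "terms")
  expect_equal(as.numeric(sum(terms)), as.numeric(got))
})

test_that("full fit decomposes its loss into data term plus penalties", {
  sw <- generate_pulse_sweep(nbox, voltages = c(2, 4),
                             proto = pulse_protocol(noise_sd = 0,
                                                    n_pulses = 3), seed = 1)
  f <- fit_full(sw, tau = 11.7, steps = 0)
  lt <- f$loss_terms
  pen <- sum(lt[c("anchor_wmin", "overshoot", "nonneg", "anchor_beta",
                  "read")])
  expect_equal(f$loss, lt[["sse"]] + pen, tolerance = 1e-12)
  # zero-step fit returns its initialization unchanged
  expect_equal(unname(coef(f)[c("beta", "w_min")]), c(0.5, 0.15))
})

test_that("full fit recovers the tunneling and potentiation constants", {
  sw <- generate_pulse_sweep(nbox, proto = pulse_protocol(noise_sd = 0),
                             seed = 1)
  gmin_eff <- device_current(nbox, nbox$w_min, 0.7) / 0.7
  f <- fit_full(sw, tau = 11.7, read_conductance = gmin_eff,
                optimizer = "lbfgs", steps = 4000)
  cf <- coef(f)
  for (nm in c("gamma", "delta", "eta", "lam"))
    expect_lt(abs(cf[[nm]] / nbox[[nm]] - 1), 0.15)
  # beta is held by its anchor; the data cannot identify it
  expect_lt(abs(cf[["beta"]] - 0.5), 0.05)
})

test_that("disabling constraints removes every penalty term", {
  sw <- generate_pulse_sweep(nbox, voltages = c(2, 4),
                             proto = pulse_protocol(noise_sd = 0,
                                                    n_pulses = 3), seed = 1)
  f <- fit_full(sw, tau = 11.7, steps = 0, constraints = FALSE)
  pen <- f$loss_terms[c("anchor_wmin", "overshoot", "nonneg", "anchor_beta",
                        "read")]
  expect_true(all(pen == 0))
  expect_equal(f$loss, f$loss_terms[["sse"]])
})

test_that("scaling search recovers known scales from hybrid ground truth", {
  s_true <- scaling_factors(0.12, 1.5, 0.5)
  stim <- ou_process(150, seed = 3)
  gtruth <- simulate_hybrid(hh0, nbox, s_true, stim)
  fs <- fit_scaling(gtruth$V_mV, hh0, nbox, stim, seed = 4, max_gen = 100,
                    restarts = 0)
  cf <- coef(fs)
  expect_lt(abs(cf[["V_scale"]] / 0.12 - 1), 0.05)
  expect_lt(abs(cf[["T_scale"]] / 1.5 - 1), 0.05)
  expect_lt(abs(cf[["I_scale"]] / 0.5 - 1), 0.05)
  expect_lt(fs$score, 1)
})

test_that("scaling-search score equals the post-transient MSE contract", {
  stim <- ou_process(120, seed = 13)
  gtruth <- simulate_hh(hh0, stim)
  fs <- fit_scaling(gtruth, hh0, nbox, stim, seed = 1, max_gen = 30,
                    restarts = 0)
  hy <- simulate_hybrid(hh0, nbox, fs$scales, stim)
  expect_equal(fs$score, mse_score(gtruth, hy, discard = 25),
               tolerance = 1e-10)
  # the incumbent cannot be worse than identity scaling (which may diverge,
  # counting as an infinitely poor candidate)
  id_mse <- tryCatch(
    mse_score(gtruth, simulate_hybrid(hh0, nbox, scaling_factors(1, 1, 1),
                                      stim), discard = 25),
    error = function(e) Inf)
  expect_lte(fs$score, id_mse)
})

test_that("sensitivity scan samples the requested ranges and scores", {
  stim <- ou_process(80, seed = 14)
  gtruth <- simulate_hh(hh0, stim)
  expect_equal(nrow(sensitivity_scan(gtruth, hh0, nbox, stim,
                                     n_samples = 0)), 0)
  sc <- sensitivity_scan(gtruth, hh0, nbox, stim, n_samples = 30, seed = 2)
  expect_equal(nrow(sc), 30)
  expect_true(all(sc$V_scale >= 1e-3 & sc$V_scale <= 1e3))
  expect_true(all(sc$mse > 0))
})

test_that("long-horizon R2 is 1 for self-comparison and bounded above", {
  stim <- ou_process(100, seed = 15)
  gtruth <- simulate_hh(hh0, stim)
  expect_equal(r2_score(gtruth, gtruth), 1)
  r2 <- evaluate_r2(hh0, nbox, s_nbox, horizon = 40, multiplier = 2,
                    seed = 15)
  expect_lte(r2, 1)
})

test_that("CMA-ES minimises simple benchmarks within bounds", {
  sphere <- function(x) sum((x - c(1, -2, 0.5))^2)
  r <- cma_es(sphere, c(0, 0, 0), sigma0 = 1, lower = -5, upper = 5,
              seed = 1)
  expect_lt(r$value, 1e-8)
  expect_equal(r$par, c(1, -2, 0.5), tolerance = 1e-3)
  rosen <- function(x) 100 * (x[2] - x[1]^2)^2 + (1 - x[1])^2
  r2 <- cma_es(rosen, c(-1, 1), sigma0 = 0.5, lower = -3, upper = 3,
               max_gen = 400, seed = 2)
  expect_lt(r2$value, 1e-6)
  # bound handling: optimum outside the box lands on the boundary
  rb <- cma_es(function(x) sum((x - 10)^2), c(0, 0), sigma0 = 1,
               lower = -1, upper = 1, seed = 3)
  expect_equal(rb$par, c(1, 1), tolerance = 1e-6)
  # determinism given the seed
  ra <- cma_es(sphere, c(0, 0, 0), sigma0 = 1, lower = -5, upper = 5,
               seed = 5, max_gen = 40)
  rbb <- cma_es(sphere, c(0, 0, 0), sigma0 = 1, lower = -5, upper = 5,
                seed = 5, max_gen = 40)
  expect_identical(ra$par, rbb$par)
})
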