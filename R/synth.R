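#' Ornstein-Uhlenbeck stimulus
#'
#' Euler-Maruyama discretisation of \eqn{dX = -\theta X\,dt + \sigma\,dW},
#' returned as \code{gain * X}. This is the noisy current drive used for all
#' neuron simulations; defaults are the study conditions
#' (\eqn{\theta = 0.1}/ms, \eqn{\sigma = 0.7}, gain 4).
#'
#' @param duration length of the trace (ms).
#' @param dt sampling step (ms).
#' @param theta mean-reversion rate (1/ms).
#' @param sigma noise intensity.
#' @param gain multiplier applied to the process before output.
#' @param seed RNG seed (integer); the trace is a pure function of the
#'   arguments.
#' @param x0 initial value of the underlying process.
#' @return A [ts_trace()] with channel \code{i_app}.
#' @export
ou_process <- function(duration, dt = 0.005, theta = 0.1, sigma = 0.7,
                       gain = 4, seed = 0, x0 = 0) {
  stopifnot(duration > 0, dt > 0, theta > 0, sigma >= 0)
  n <- round(duration / dt)
  old <- .save_seed(seed)
  on.exit(.restore_seed(old))
  z <- stats::rnorm(n - 1)
  # X[k+1] = (1 - theta dt) X[k] + sigma sqrt(dt) Z[k]  -- AR(1) recursion
  x <- stats::filter(c(x0, sigma * sqrt(dt) * z), 1 - theta * dt,
                     method = "recursive")
  ts_trace(data.frame(i_app = gain * as.numeric(x)), dt = dt,
           units = c(i_app = "uA/cm2"))
}

.save_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  old
}

.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Reduced conductance-model parameters
#'
#' Three-constant model of the fixed-voltage potentiation/decay experiment:
#' conductance relaxes to \code{G_min} with time constant \code{tau} and
#' grows at rate \code{A} while the write pulse is on.
#'
#' @param tau decay time constant (ms).
#' @param A potentiation rate (uS/ms).
#' @param G_min baseline conductance (uS).
#' @return An object of class \code{"reduced_params"}.
#' @export
reduced_params <- function(tau, A, G_min) {
  if (any(c(tau, A, G_min) <= 0)) stop("tau, A and G_min must be > 0")
  structure(list(tau = tau, A = A, G_min = G_min), class = "reduced_params")
}

#' @export
print.reduced_params <- function(x, ...) {
  cat(sprintf("Reduced model: tau = %g ms, A = %g uS/ms, G_min = %g uS\n",
              x$tau, x$A, x$G_min))
  invisible(x)
}

#' Write/read pulse protocol
#'
#' Geometry of the synthetic device-characterisation experiments: trains of
#' fixed-amplitude write pulses with decay intervals in between, sampled at
#' a read voltage.
#'
#' @param write_V write-pulse amplitude (V).
#' @param write_ms write-pulse duration (ms).
#' @param gap_ms inter-pulse interval (ms).
#' @param read_V read voltage used to sample conductance/current (V).
#' @param n_pulses pulses per train.
#' @param replicate how many times the train is replicated end-to-end
#'   (the fitting stage replicates the recorded trace tenfold).
#' @param noise_sd relative s.d. of multiplicative Gaussian measurement
#'   noise; 0 for noiseless data.
#' @param dt sampling/integration step (ms).
#' @return An object of class \code{"pulse_protocol"}.
#' @export
pulse_protocol <- function(write_V = 4, write_ms = 10, gap_ms = 50,
                           read_V = 0.7, n_pulses = 10, replicate = 10,
                           noise_sd = 0, dt = 0.05) {
  stopifnot(write_V >= 0, read_V >= 0, write_ms > 0, gap_ms > 0,
            n_pulses >= 1, replicate >= 1, noise_sd >= 0, dt > 0)
  structure(list(write_V = write_V, write_ms = write_ms, gap_ms = gap_ms,
                 read_V = read_V, n_pulses = n_pulses, replicate = replicate,
                 noise_sd = noise_sd, dt = dt), class = "pulse_protocol")
}

#' Pulse-train voltage waveform for a protocol
#'
#' @param proto a [pulse_protocol()].
#' @param write_V optional override of the write amplitude.
#' @return Numeric vector of voltages sampled at \code{proto$dt} for one
#'   replication of the train.
#' @export
pulse_waveform <- function(proto, write_V = proto$write_V) {
  n_on <- round(proto$write_ms / proto$dt)
  n_off <- round(proto$gap_ms / proto$dt)
  rep(rep(c(write_V, 0), proto$n_pulses), rep(c(n_on, n_off), proto$n_pulses))
}

#' Simulate the reduced conductance model
#'
#' Forward-Euler integration of \eqn{\dot G = -(G - G_{min})/\tau + A} while
#' the write pulse is on, decay only otherwise.
#'
#' @param rp a [reduced_params()] object.
#' @param V voltage waveform (vector, V); potentiation is applied where
#'   \code{V > 0}.
#' @param dt step (ms).
#' @param G0 initial conductance; defaults to \code{G_min}.
#' @return Numeric vector of conductances (uS) aligned with \code{V}.
#' @export
simulate_reduced <- function(rp, V, dt, G0 = rp$G_min) {
  stopifnot(inherits(rp, "reduced_params"), dt > 0)
  cpp_reduced_sim(rp$tau, rp$A, rp$G_min, V > 0, dt, G0)
}

#' Synthetic potentiation/decay experiment
#'
#' Generates the fixed-voltage characterisation trace the first calibration
#' stage consumes: the reduced model driven by a replicated write-pulse
#' train, with optional multiplicative measurement noise.
#'
#' @param truth a [reduced_params()] object (ground-truth constants).
#' @param proto a [pulse_protocol()].
#' @param seed RNG seed for the measurement noise.
#' @return List with \code{G} (conductance \code{ts_trace}, uS) and \code{V}
#'   (voltage waveform vector, V).
#' @export
generate_potentiation_decay <- function(truth, proto = pulse_protocol(),
                                        seed = 0) {
  stopifnot(inherits(truth, "reduced_params"), inherits(proto, "pulse_protocol"))
  V <- rep(pulse_waveform(proto), proto$replicate)
  G <- simulate_reduced(truth, V, proto$dt)
  if (proto$noise_sd > 0) {
    old <- .save_seed(seed)
    on.exit(.restore_seed(old))
    G <- G * (1 + proto$noise_sd * stats::rnorm(length(G)))
  }
  list(G = ts_trace(data.frame(G_uS = G), dt = proto$dt, units = c(G_uS = "uS")),
       V = V)
}

#' Synthetic varying-voltage pulse sweep
#'
#' The second calibration stage's data: for each write amplitude the full
#' device model is integrated through a pulse train (state driven by the
#' write pulses; the read bias is applied as short non-perturbing read-outs)
#' and the measured current is recorded at every time step -- at the write
#' bias while a pulse is on, at the read voltage in between. Sampling the
#' current across the swept write amplitudes is what makes the tunneling
#' slope delta identifiable separately from gamma; read-outs at the single
#' fixed read voltage alone only constrain their product. With zero noise
#' every sample satisfies the device law exactly.
#'
#' @param truth a [memristor_params()] object (ground-truth device).
#' @param voltages write amplitudes to sweep (V).
#' @param proto a [pulse_protocol()]; \code{replicate} is ignored (each
#'   voltage runs one train).
#' @param seed RNG seed for measurement noise.
#' @return List with \code{voltages}, \code{dt}, \code{read_V} and
#'   \code{traces}: a list (one per voltage) of data.frames with columns
#'   \code{t_ms}, \code{V_drive} (state-driving waveform, V),
#'   \code{V_meas} (measurement bias, V), \code{i_uA}, \code{w}.
#' @export
generate_pulse_sweep <- function(truth, voltages = c(1, 1.5, 2, 2.5, 3, 3.5, 4),
                                 proto = pulse_protocol(), seed = 0) {
  stopifnot(inherits(truth, "memristor_params"), all(voltages >= 0))
  pv <- .mp_vec(truth)
  old <- .save_seed(seed)
  on.exit(.restore_seed(old))
  traces <- lapply(voltages, function(v) {
    Vdrive <- pulse_waveform(proto, write_V = v)
    Vmeas <- ifelse(Vdrive > 0, Vdrive, proto$read_V)
    sim <- cpp_device_sim(pv, Vdrive, truth$w_min, proto$dt)
    i <- device_current(truth, sim$w, Vmeas)
    if (proto$noise_sd > 0)
      i <- i * (1 + proto$noise_sd * stats::rnorm(length(i)))
    data.frame(t_ms = proto$dt * (seq_along(Vdrive) - 1), V_drive = Vdrive,
               V_meas = Vmeas, i_uA = i, w = sim$w)
  })
  list(voltages = voltages, dt = proto$dt, read_V = proto$read_V,
       traces = traces)
}
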