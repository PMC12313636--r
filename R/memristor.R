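#' Memristor device current
#'
#' Current through the volatile memristor at state \code{w} and bias
#' \code{V}: a Schottky-barrier contribution \eqn{(1-w)\alpha(1-e^{-\beta V})}
#' in parallel with a tunneling contribution \eqn{w\gamma\sinh(\delta V)}.
#' The current is pinched at the origin (zero at \code{V = 0} for every
#' \code{w}) and carries the sign of \code{V}.
#'
#' @param p a [memristor_params()] object.
#' @param w internal state, within \code{[w_min, w_max]}.
#' @param V applied bias (V). Arguments of the exponentials are clamped to
#'   magnitude 40 (with a warning) -- biases beyond that are unphysical for
#'   these devices.
#' @return Current in uA (vectorised over \code{w} and \code{V}).
#' @export
device_current <- function(p, w, V) {
  stopifnot(inherits(p, "memristor_params"))
  .check_w(p, w)
  .check_bias(p, V)
  (1 - w) * p$alpha * (1 - exp(-.clamp40(p$beta * V))) +
    w * p$gamma * sinh(.clamp40(p$delta * V))
}

.check_w <- function(p, w) {
  if (any(!is.finite(w)) || any(w < p$w_min - 1e-12) || any(w > p$w_max + 1e-12))
    stop(sprintf("state w out of bounds [%g, %g]", p$w_min, p$w_max))
  invisible(TRUE)
}

.clamp40 <- function(x) pmin(40, pmax(-40, x))

.check_bias <- function(p, V) {
  if (any(abs(p$eta * V) > 40) || any(abs(p$delta * V) > 40))
    warning("bias clamped: |eta*V| or |delta*V| exceeds 40 (unphysical)")
  invisible(TRUE)
}

#' State window function
#'
#' Multiplicative window \eqn{W(w) = 1 - e^{w-3}} gating the potentiation
#' term of the state equation; strictly decreasing in \code{w} and zero at
#' \code{w = 3} (well above the operating range, so it acts as a soft upper
#' brake rather than a hard bound).
#'
#' @param w internal state.
#' @return Dimensionless window value.
#' @export
memristor_window <- function(w) 1 - exp(w - 3)

#' State dynamics of the volatile memristor
#'
#' \eqn{\dot w = W(w)\,\lambda\sinh(\eta V) - (w - w_{min})/\tau}: the
#' window gates the voltage-driven potentiation term only; decay toward
#' \code{w_min} is a plain first-order relaxation.
#'
#' @inheritParams device_current
#' @return dw/dt in 1/ms.
#' @export
state_rate <- function(p, w, V) {
  stopifnot(inherits(p, "memristor_params"))
  .check_w(p, w)
  .check_bias(p, V)
  memristor_window(w) * p$lam * sinh(.clamp40(p$eta * V)) - (w - p$w_min) / p$tau
}

#' Single forward-Euler state update
#'
#' Advances the state one step of \code{dt} and clips the result to
#' \code{[w_min, w_max]} (the clip is part of the discretisation contract:
#' it prevents forward-Euler overshoot past the physical bounds).
#'
#' @inheritParams device_current
#' @param dt time step (ms), positive.
#' @return Updated state.
#' @export
step_state <- function(p, w, V, dt) {
  if (dt <= 0) stop("dt must be > 0")
  pmin(p$w_max, pmax(p$w_min, w + dt * state_rate(p, w, V)))
}

#' Steady-state internal state under constant bias
#'
#' Ignoring the window, the state equation balances at
#' \eqn{w_\infty = w_{min} + \tau\lambda\sinh(\eta V)}, clipped to the state
#' bounds: \code{w_min} at zero bias, saturating at \code{w_max} for
#' \eqn{V \ge \sinh^{-1}((w_{max})/(\tau\lambda))/\eta}. The sigmoidal shape in
#' V mirrors the steady state of the potassium activation gate.
#'
#' @inheritParams device_current
#' @return Steady-state value of \code{w} (vectorised over \code{V}).
#' @export
steady_state_w <- function(p, V) {
  stopifnot(inherits(p, "memristor_params"))
  pmin(p$w_max, pmax(p$w_min, p$w_min + p$tau * p$lam * sinh(.clamp40(p$eta * V))))
}

#' Effective state time constant under constant bias
#'
#' Near \code{w_min} the relaxation time of the state is \eqn{\tau} for weak
#' drive (\eqn{\tau\lambda\sinh(\eta V) < 1}) and
#' \eqn{1/(\lambda\sinh(\eta V))} for strong drive -- the voltage-dependent
#' time constant that makes the device resemble the potassium gate.
#'
#' @inheritParams device_current
#' @return Effective time constant (ms).
#' @export
effective_time_constant <- function(p, V) {
  stopifnot(inherits(p, "memristor_params"), all(V >= 0))
  drive <- p$tau * p$lam * sinh(.clamp40(p$eta * V))
  ifelse(drive < 1, p$tau, 1 / (p$lam * sinh(.clamp40(p$eta * V))))
}

#' Small-signal linearization of the device current
#'
#' First-order expansion of the i(V) characteristic around V = 0:
#' \eqn{i \approx w(\gamma\delta - \alpha\beta)V + \alpha\beta V}. The state
#' enters linearly as a conductance, plus a persistent Schottky leak
#' conductance \eqn{\alpha\beta}.
#'
#' @inheritParams device_current
#' @return Current in uA.
#' @export
linearized_current <- function(p, w, V) {
  stopifnot(inherits(p, "memristor_params"))
  w * (p$gamma * p$delta - p$alpha * p$beta) * V + p$alpha * p$beta * V
}

#' Hypothetical linear-conductance device law
#'
#' A device whose conductance depends linearly on the internal state --
#' the linearization above promoted to a full device law (including the
#' Schottky leak term). Offered as a drop-in replacement law in
#' [simulate_hybrid()] to probe how much of the hybrid neuron's reduced
#' spike height is due to the sinh-shaped tunneling current.
#'
#' @inheritParams device_current
#' @return Current in uA.
#' @export
linear_variant_current <- function(p, w, V) linearized_current(p, w, V)

#' I-V hysteresis loop under sinusoidal drive
#'
#' Drives the device with \code{V(t) = amplitude * sin(2 pi freq t)} and
#' integrates the state with forward Euler. The resulting I-V trajectory is
#' the pinched hysteresis loop characteristic of a memristor: the current is
#' exactly zero at every zero-crossing of the voltage.
#'
#' @inheritParams device_current
#' @param amplitude drive amplitude (V).
#' @param freq drive frequency (cycles/ms); loop area is largest when the
#'   drive period is comparable to \code{tau}.
#' @param dt integration step (ms).
#' @param cycles number of drive periods.
#' @param w0 initial state; defaults to \code{w_min}.
#' @return A [ts_trace()] with channels \code{V_volts}, \code{i_uA}, \code{w}.
#' @export
hysteresis_trace <- function(p, amplitude, freq, dt = 0.005, cycles = 3,
                             w0 = p$w_min) {
  stopifnot(inherits(p, "memristor_params"), freq > 0, dt > 0, cycles >= 1)
  n <- ceiling(cycles / (freq * dt))
  t <- dt * (seq_len(n) - 1)
  V <- amplitude * sin(2 * pi * freq * t)
  sim <- cpp_device_sim(.mp_vec(p), V, w0, dt)
  ts_trace(data.frame(V_volts = V, i_uA = sim$i, w = sim$w), dt = dt,
           units = c(V_volts = "V", i_uA = "uA", w = "1"))
}
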