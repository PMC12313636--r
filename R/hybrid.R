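#' Memristor-emulated potassium current
#'
#' The device current evaluated at the scaled driving voltage
#' \eqn{V_{dev} = V_{scale}(v - E_K)} and mapped back to membrane units by
#' \code{I_scale}. Zero at \code{v = E_K} for every state and scaling.
#'
#' @param p a [memristor_params()] object.
#' @param s a [scaling_factors()] object.
#' @param w device state.
#' @param v membrane potential (mV).
#' @param E_K potassium reversal potential (mV).
#' @param law device law: \code{"sinh"} (physical device) or
#'   \code{"linear"} (linear-conductance variant).
#' @return Current density (uA/cm^2).
#' @export
memristor_k_current <- function(p, s, w, v, E_K, law = c("sinh", "linear")) {
  stopifnot(inherits(p, "memristor_params"), inherits(s, "scaling_factors"))
  law <- match.arg(law)
  Vdev <- s$V_scale * (v - E_K)
  if (law == "linear")
    s$I_scale * linear_variant_current(p, w, Vdev)
  else
    s$I_scale * device_current(p, w, Vdev)
}

#' State dynamics of the emulated potassium channel
#'
#' \code{T_scale * state_rate(p, w, V_scale*(v - E_K))}: the device state
#' equation driven by the scaled membrane voltage and sped up by
#' \code{T_scale}.
#'
#' @inheritParams memristor_k_current
#' @return dw/dt in 1/ms (membrane time).
#' @export
memristor_k_rate <- function(p, s, w, v, E_K) {
  stopifnot(inherits(p, "memristor_params"), inherits(s, "scaling_factors"))
  s$T_scale * state_rate(p, w, s$V_scale * (v - E_K))
}

#' Simulate the hybrid (memristor-potassium) neuron
#'
#' The Hodgkin-Huxley membrane with the potassium channel replaced by the
#' scaled memristor: sodium and leak channels are untouched, the n gate is
#' replaced by the device state w. Integrated by Euler-Maruyama at a fixed
#' step from \code{V(0) = -60} mV, \code{w(0) = w_min}.
#'
#' @param hh an [hh_params()] object (its \code{g_K} is unused).
#' @param mem a [memristor_params()] object.
#' @param s a [scaling_factors()] object.
#' @param stimulus applied current, as in [simulate_hh()].
#' @param dt integration step (ms).
#' @param law \code{"sinh"} or \code{"linear"} device law.
#' @param init named vector \code{V, m, h, w}; defaults to \code{V = -60},
#'   gates at steady state, \code{w = w_min}.
#' @return A [ts_trace()] with channels \code{V_mV, m, h, w, i_K, i_app};
#'   \code{i_K} is the emulated potassium current in uA/cm^2.
#' @export
simulate_hybrid <- function(hh, mem, s, stimulus, dt = 0.005,
                            law = c("sinh", "linear"), init = NULL) {
  stopifnot(inherits(hh, "hh_params"), inherits(mem, "memristor_params"),
            inherits(s, "scaling_factors"))
  law <- match.arg(law)
  iapp <- .stimulus_vector(stimulus, dt)
  if (is.null(init)) {
    g <- gate_steady(-60)
    init <- c(V = -60, m = g$m_inf, h = g$h_inf, w = mem$w_min)
  }
  m <- cpp_hybrid_sim(.hh_vec(hh), .mp_vec(mem),
                      s$V_scale, s$T_scale, s$I_scale, iapp, dt,
                      init[["V"]], init[["m"]], init[["h"]], init[["w"]],
                      law == "linear")
  div <- attr(m, "diverged")
  if (!is.null(div) && div >= 0)
    stop(sprintf("hybrid simulation diverged (|V| > 500 mV) at t = %g ms",
                 div * dt))
  ts_trace(data.frame(V_mV = m[, 1], m = m[, 2], h = m[, 3], w = m[, 4],
                      i_K = m[, 5], i_app = iapp),
           dt = dt, units = c(V_mV = "mV", i_K = "uA/cm2", i_app = "uA/cm2"))
}

#' Physical passive-component values implied by the scaling factors
#'
#' Re-scaling the hybrid equations is equivalent to building the physical
#' circuit with re-scaled passive components. In the physical circuit the
#' potassium element is the device itself, so the membrane-unit potassium
#' current is \code{I_scale} times the device current; circuit equivalence
#' under \eqn{V' = V_{scale} V}, \eqn{t' = T_{scale} t},
#' \eqn{i' = i / I_{scale}} then fixes
#' \eqn{E'_x = V_{scale} E_x}, \eqn{R'_L = V_{scale} I_{scale} R_L} and
#' \eqn{C'_m = (T_{scale} / (V_{scale} I_{scale})) C_m} as the unique
#' scaled component values (see the round-trip equivalence test).
#'
#' @param hh an [hh_params()] object.
#' @param s a [scaling_factors()] object.
#' @return Named list: \code{E_Na, E_K, E_L} (V), \code{R_L}
#'   (scaled leak resistance), \code{C_m} (scaled capacitance),
#'   \code{g_Na} (scaled sodium conductance).
#' @export
scale_passive <- function(hh, s) {
  stopifnot(inherits(hh, "hh_params"), inherits(s, "scaling_factors"))
  list(E_Na = s$V_scale * hh$E_Na,
       E_K  = s$V_scale * hh$E_K,
       E_L  = s$V_scale * hh$E_L,
       R_L  = s$V_scale * s$I_scale * (1 / hh$g_L),
       C_m  = hh$C_m * s$T_scale / (s$V_scale * s$I_scale),
       g_Na = hh$g_Na / (s$V_scale * s$I_scale))
}

#' Steady-state potassium current: HH channel vs memristor replacement
#'
#' For each voltage on a grid, the HH channel's steady current
#' \eqn{g_K n_\infty(v)^4 (v - E_K)} and the memristor replacement's steady
#' current at \eqn{w = w_\infty}. Both vanish at \code{v = E_K}; the
#' sinh-shaped tunneling term makes the memristor current surge at large
#' depolarisations, which is what limits the hybrid spike height.
#'
#' @param hh an [hh_params()] object.
#' @param mem a [memristor_params()] object.
#' @param s a [scaling_factors()] object.
#' @param v voltage grid (mV).
#' @return data.frame with columns \code{v, i_K_hh, i_K_mem} (uA/cm^2).
#' @export
steady_state_comparison <- function(hh, mem, s,
                                    v = seq(-90, 40, by = 1)) {
  g <- gate_steady(v)
  winf <- steady_state_w(mem, s$V_scale * (v - hh$E_K))
  data.frame(v = v,
             i_K_hh = k_channel_current(hh, v, g$n_inf),
             i_K_mem = memristor_k_current(mem, s, winf, v, hh$E_K))
}
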