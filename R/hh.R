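#' Hodgkin-Huxley gate rate functions
#'
#' The canonical squid-axon opening/closing rates for the n, m and h gates
#' (modern sign convention, resting potential near -65 mV). Removable
#' singularities of the alpha_n and alpha_m expressions are handled by their
#' limiting values.
#'
#' @param V membrane potential (mV), vectorised.
#' @return A data.frame with columns \code{alpha_n, beta_n, alpha_m, beta_m,
#'   alpha_h, beta_h} (1/ms).
#' @export
gate_rates <- function(V) {
  stopifnot(all(is.finite(V)))
  m <- cpp_gate_rates(as.numeric(V))
  out <- as.data.frame(m)
  names(out) <- c("alpha_n", "beta_n", "alpha_m", "beta_m", "alpha_h", "beta_h")
  out
}

#' Gate steady states and time constants
#'
#' \code{x_inf = alpha/(alpha+beta)}, \code{tau_x = 1/(alpha+beta)} for each
#' gate. \code{n_inf} is the sigmoidal steady state of the potassium gate
#' that the memristor state emulates.
#'
#' @inheritParams gate_rates
#' @return data.frame with columns \code{n_inf, tau_n, m_inf, tau_m, h_inf,
#'   tau_h}.
#' @export
gate_steady <- function(V) {
  r <- gate_rates(V)
  data.frame(
    n_inf = r$alpha_n / (r$alpha_n + r$beta_n),
    tau_n = 1 / (r$alpha_n + r$beta_n),
    m_inf = r$alpha_m / (r$alpha_m + r$beta_m),
    tau_m = 1 / (r$alpha_m + r$beta_m),
    h_inf = r$alpha_h / (r$alpha_h + r$beta_h),
    tau_h = 1 / (r$alpha_h + r$beta_h))
}

#' Hodgkin-Huxley state derivatives
#'
#' @param p an [hh_params()] object.
#' @param s named list or vector with elements \code{V, n, m, h}.
#' @param i_app applied current density (uA/cm^2).
#' @return Named vector of derivatives \code{dV, dn, dm, dh}.
#' @export
hh_derivatives <- function(p, s, i_app = 0) {
  stopifnot(inherits(p, "hh_params"))
  s <- as.list(s)
  r <- gate_rates(s$V)
  dV <- (i_app -
           p$g_Na * s$m^3 * s$h * (s$V - p$E_Na) -
           p$g_K * s$n^4 * (s$V - p$E_K) -
           p$g_L * (s$V - p$E_L)) / p$C_m
  c(dV = dV,
    dn = r$alpha_n * (1 - s$n) - r$beta_n * s$n,
    dm = r$alpha_m * (1 - s$m) - r$beta_m * s$m,
    dh = r$alpha_h * (1 - s$h) - r$beta_h * s$h)
}

#' Potassium channel current
#'
#' \eqn{i_K = g_K n^4 (V - E_K)}; zero at the reversal potential for any
#' gate value.
#'
#' @inheritParams hh_derivatives
#' @param V membrane potential (mV).
#' @param n potassium gate value.
#' @return Current density (uA/cm^2).
#' @export
k_channel_current <- function(p, V, n) {
  stopifnot(inherits(p, "hh_params"))
  p$g_K * n^4 * (V - p$E_K)
}

#' Resting state of the HH membrane
#'
#' Solves the zero-current fixed point by bisection on V with gates at
#' steady state.
#'
#' @inheritParams hh_derivatives
#' @return Named vector \code{V, n, m, h} at rest.
#' @export
hh_rest <- function(p) {
  stopifnot(inherits(p, "hh_params"))
  f <- function(V) {
    g <- gate_steady(V)
    -(p$g_Na * g$m_inf^3 * g$h_inf * (V - p$E_Na) +
        p$g_K * g$n_inf^4 * (V - p$E_K) +
        p$g_L * (V - p$E_L))
  }
  V <- stats::uniroot(f, c(-90, -40), tol = 1e-10)$root
  g <- gate_steady(V)
  c(V = V, n = g$n_inf, m = g$m_inf, h = g$h_inf)
}

#' Simulate the Hodgkin-Huxley neuron
#'
#' Forward-Euler (Euler-Maruyama when the stimulus is a noise realization)
#' integration of the full four-state model at a fixed step.
#'
#' @param p an [hh_params()] object.
#' @param stimulus applied current: either a numeric vector sampled at
#'   \code{dt} (uA/cm^2) or a \code{ts_trace} with channel \code{i_app}.
#' @param dt integration step (ms); default 0.005.
#' @param init named vector \code{V, n, m, h}; default \code{V = -60} mV with
#'   gates at their steady state for that voltage.
#' @return A [ts_trace()] with channels \code{V_mV, n, m, h, i_app}.
#' @export
simulate_hh <- function(p, stimulus, dt = 0.005, init = NULL) {
  stopifnot(inherits(p, "hh_params"))
  iapp <- .stimulus_vector(stimulus, dt)
  if (is.null(init)) {
    g <- gate_steady(-60)
    init <- c(V = -60, n = g$n_inf, m = g$m_inf, h = g$h_inf)
  }
  m <- cpp_hh_sim(.hh_vec(p), iapp, dt, init[["V"]], init[["n"]],
                  init[["m"]], init[["h"]])
  ts_trace(data.frame(V_mV = m[, 1], n = m[, 2], m = m[, 3], h = m[, 4],
                      i_app = iapp),
           dt = dt, units = c(V_mV = "mV", i_app = "uA/cm2"))
}

.stimulus_vector <- function(stimulus, dt) {
  if (inherits(stimulus, "ts_trace")) {
    if (abs(attr(stimulus, "dt") - dt) > 1e-12)
      stop("stimulus dt does not match integrator dt")
    if (!"i_app" %in% names(stimulus))
      stop("stimulus trace must have an i_app channel")
    as.numeric(stimulus$i_app)
  } else {
    as.numeric(stimulus)
  }
}
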