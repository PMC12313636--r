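#' Volatile memristor device parameters
#'
#' Constructs the eight-constant compact model of a volatile oxygen-vacancy
#' memristor. The device current has a Schottky-barrier term
#' \eqn{(1-w)\,\alpha\,(1-e^{-\beta V})} in parallel with a tunneling term
#' \eqn{w\,\gamma\,\sinh(\delta V)}; the internal state \eqn{w} potentiates
#' under bias at rate \eqn{\lambda \sinh(\eta V)} (gated by a window
#' function) and decays back to \code{w_min} with time constant \code{tau}.
#'
#' @param tau decay time constant (ms); must be positive.
#' @param alpha Schottky current scale (uA).
#' @param beta Schottky voltage slope (1/V).
#' @param gamma tunneling current scale (uA).
#' @param delta tunneling voltage slope (1/V).
#' @param eta potentiation voltage slope (1/V).
#' @param lam potentiation rate scale (1/ms).
#' @param w_min lower bound of the internal state (dimensionless).
#' @param w_max upper bound of the internal state; the integrator clips the
#'   state to \code{[w_min, w_max]} after every step. Default 0.99.
#' @return An object of class \code{"memristor_params"}.
#' @seealso [device_preset()] for the fitted NbOx and WOx parameter sets,
#'   [device_current()], [state_rate()].
#' @export
memristor_params <- function(tau, alpha, beta, gamma, delta, eta, lam,
                             w_min, w_max = 0.99) {
  vals <- c(tau = tau, alpha = alpha, beta = beta, gamma = gamma,
            delta = delta, eta = eta, lam = lam, w_min = w_min, w_max = w_max)
  if (!all(is.finite(vals)))
    stop("all memristor parameters must be finite")
  if (tau <= 0) stop("tau must be > 0")
  if (any(c(alpha, beta, gamma, delta, eta, lam) < 0))
    stop("alpha, beta, gamma, delta, eta and lam must be >= 0")
  if (!(w_min > 0 && w_min < w_max && w_max <= 1))
    stop("state bounds must satisfy 0 < w_min < w_max <= 1")
  structure(as.list(vals), class = "memristor_params")
}

#' Fitted device presets
#'
#' Parameter sets for the NbOx and WOx volatile memristors, read from the
#' JSON preset files shipped with the package. The WOx decay constant is
#' 50 ms (the tungsten-oxide device potentiates fast but decays an order of
#' magnitude slower than NbOx).
#'
#' @param device \code{"nbox"} or \code{"wox"}.
#' @return A \code{"memristor_params"} object.
#' @examples
#' device_preset("nbox")
#' @export
device_preset <- function(device = c("nbox", "wox")) {
  device <- match.arg(device)
  path <- system.file("extdata", "presets", paste0(device, ".json"),
                      package = "memhh", mustWork = TRUE)
  do.call(memristor_params, jsonlite::read_json(path, simplifyVector = TRUE))
}

.mp_vec <- function(p) {
  unlist(p[c("tau", "alpha", "beta", "gamma", "delta", "eta", "lam",
             "w_min", "w_max")])
}

#' @export
print.memristor_params <- function(x, ...) {
  cat("Volatile memristor parameters\n")
  v <- .mp_vec(x)
  cat(sprintf("  tau = %g ms, alpha = %g uA, beta = %g /V, gamma = %g uA\n",
              v["tau"], v["alpha"], v["beta"], v["gamma"]))
  cat(sprintf("  delta = %g /V, eta = %g /V, lam = %g /ms\n",
              v["delta"], v["eta"], v["lam"]))
  cat(sprintf("  state bounds [%g, %g]\n", v["w_min"], v["w_max"]))
  invisible(x)
}

#' Hodgkin-Huxley membrane parameters
#'
#' Canonical squid-axon conductance parameters in the modern convention
#' (resting potential near -65 mV). All values can be overridden.
#'
#' @param C_m membrane capacitance (uF/cm^2).
#' @param g_Na,g_K,g_L maximal conductances (mS/cm^2).
#' @param E_Na,E_K,E_L reversal potentials (mV).
#' @return An object of class \code{"hh_params"}.
#' @export
hh_params <- function(C_m = 1, g_Na = 120, g_K = 36, g_L = 0.3,
                      E_Na = 50, E_K = -77, E_L = -54.4) {
  if (C_m <= 0) stop("C_m must be > 0")
  if (any(c(g_Na, g_K, g_L) < 0)) stop("conductances must be >= 0")
  if (!(E_Na > E_L && E_L > E_K))
    stop("reversal potentials must satisfy E_Na > E_L > E_K")
  structure(list(C_m = C_m, g_Na = g_Na, g_K = g_K, g_L = g_L,
                 E_Na = E_Na, E_K = E_K, E_L = E_L), class = "hh_params")
}

.hh_vec <- function(p) {
  unlist(p[c("C_m", "g_Na", "g_K", "g_L", "E_Na", "E_K", "E_L")])
}

#' @export
print.hh_params <- function(x, ...) {
  cat("Hodgkin-Huxley parameters\n")
  cat(sprintf("  C_m = %g uF/cm^2; g_Na = %g, g_K = %g, g_L = %g mS/cm^2\n",
              x$C_m, x$g_Na, x$g_K, x$g_L))
  cat(sprintf("  E_Na = %g, E_K = %g, E_L = %g mV\n", x$E_Na, x$E_K, x$E_L))
  invisible(x)
}

#' Voltage/time/current scaling factors
#'
#' The re-scaling between membrane units (mV, ms, uA/cm^2) and device units
#' (V, device-ms, uA). Scaling the hybrid equations by these factors is
#' equivalent to scaling the passive components of the physical circuit
#' (see [scale_passive()]).
#'
#' @param V_scale volts of device bias per mV of membrane potential.
#' @param T_scale device time units per ms of biological time.
#' @param I_scale uA of device current per uA/cm^2 of membrane current.
#' @return An object of class \code{"scaling_factors"}.
#' @export
scaling_factors <- function(V_scale, T_scale, I_scale) {
  if (any(c(V_scale, T_scale, I_scale) <= 0))
    stop("all scaling factors must be > 0")
  structure(list(V_scale = V_scale, T_scale = T_scale, I_scale = I_scale),
            class = "scaling_factors")
}

#' Fitted scaling-factor presets
#'
#' The scaling factors found by the CMA-ES search for each device preset,
#' read from the JSON preset files shipped with the package.
#'
#' @param device \code{"nbox"} or \code{"wox"}.
#' @return A \code{"scaling_factors"} object.
#' @export
scaling_preset <- function(device = c("nbox", "wox")) {
  device <- match.arg(device)
  path <- system.file("extdata", "presets", paste0("scales_", device, ".json"),
                      package = "memhh", mustWork = TRUE)
  do.call(scaling_factors, jsonlite::read_json(path, simplifyVector = TRUE))
}

#' @export
print.scaling_factors <- function(x, ...) {
  cat(sprintf(
    "Scaling factors: V_scale = %g volt/mV, T_scale = %g, I_scale = %g uA/(uA/cm^2)\n",
    x$V_scale, x$T_scale, x$I_scale))
  invisible(x)
}
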