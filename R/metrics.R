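#' Spike detection by threshold crossing
#'
#' Upward crossings of a voltage threshold with refractory suppression; each
#' spike's peak is the maximum voltage before the trace falls back below
#' threshold.
#'
#' @param V voltage trace: a numeric vector or a \code{ts_trace} with a
#'   \code{V_mV} channel.
#' @param dt sampling step (ms); taken from the trace when one is given.
#' @param threshold detection threshold (mV). The default (-30 mV) detects
#'   both full-height HH spikes and the reduced-height hybrid spikes.
#' @param refractory minimum spacing between detections (ms).
#' @return An object of class \code{"spike_train"}: list with
#'   \code{times_ms}, \code{peaks_mV}, \code{threshold}, \code{refractory},
#'   \code{duration_ms}.
#' @export
detect_spikes <- function(V, dt = NULL, threshold = -30, refractory = 2) {
  if (inherits(V, "ts_trace")) {
    dt <- attr(V, "dt")
    V <- V$V_mV
  }
  stopifnot(is.numeric(V), !is.null(dt), dt > 0)
  above <- V > threshold
  ups <- which(!above[-length(above)] & above[-1]) + 1L
  times <- numeric(0); peaks <- numeric(0)
  last <- -Inf
  for (k in ups) {
    t_k <- (k - 1) * dt
    if (t_k - last < refractory) next
    down <- which(!above[k:length(above)])[1]
    end <- if (is.na(down)) length(V) else k + down - 2L
    times <- c(times, t_k)
    peaks <- c(peaks, max(V[k:end]))
    last <- t_k
  }
  structure(list(times_ms = times, peaks_mV = peaks, threshold = threshold,
                 refractory = refractory, duration_ms = length(V) * dt),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("Spike train: %d spikes in %g ms (%.1f Hz), threshold %g mV\n",
              length(x$times_ms), x$duration_ms,
              1000 * length(x$times_ms) / x$duration_ms, x$threshold))
  invisible(x)
}

#' Firing rate of a spike train
#' @param st a \code{spike_train}.
#' @return Rate in Hz.
#' @export
spike_rate <- function(st) 1000 * length(st$times_ms) / st$duration_ms

#' Relative spike-height reduction between two traces
#'
#' Compares mean spike peak height above the resting baseline between a
#' reference and a test trace: \code{1 - mean(test height)/mean(ref height)}.
#' The baseline is the initial (pre-stimulus) resting voltage of each trace.
#'
#' @param reference,test voltage traces (\code{ts_trace} with \code{V_mV},
#'   or numeric vectors with \code{dt} supplied).
#' @param dt sampling step when vectors are given (ms).
#' @param baseline_ms length of the initial segment averaged as resting
#'   baseline.
#' @param threshold,refractory spike-detection settings.
#' @return Fractional reduction (0.4 means the test spikes are 40\% lower).
#' @export
spike_height_reduction <- function(reference, test, dt = NULL,
                                   baseline_ms = 5,
                                   threshold = -30, refractory = 2) {
  h <- function(x) {
    if (inherits(x, "ts_trace")) { d <- attr(x, "dt"); v <- x$V_mV }
    else { d <- dt; v <- x }
    stopifnot(!is.null(d))
    base <- mean(v[seq_len(max(1, round(baseline_ms / d)))])
    st <- detect_spikes(v, dt = d, threshold = threshold,
                        refractory = refractory)
    if (!length(st$peaks_mV)) stop("no spikes detected in trace")
    mean(st$peaks_mV) - base
  }
  1 - h(test) / h(reference)
}

#' Mean squared error after transient removal
#'
#' MSE between two aligned traces with the initial transient discarded
#' before comparison.
#'
#' @param a,b numeric vectors or \code{ts_trace}s with \code{V_mV}.
#' @param dt sampling step for vectors (ms).
#' @param discard initial transient to drop (ms); default 25.
#' @return MSE over the retained samples.
#' @export
mse_score <- function(a, b, dt = NULL, discard = 25) {
  va <- .score_vec(a, dt); vb <- .score_vec(b, dt)
  stopifnot(length(va$v) == length(vb$v))
  keep <- seq_along(va$v) > round(discard / va$dt)
  mean((va$v[keep] - vb$v[keep])^2)
}

#' Coefficient of determination between two traces
#'
#' \eqn{R^2 = 1 - SS_{res}/SS_{tot}} of \code{b} as a prediction of
#' \code{a}, after transient removal; at most 1, and non-positive for a
#' predictor no better than the mean.
#'
#' @inheritParams mse_score
#' @return R-squared value.
#' @export
r2_score <- function(a, b, dt = NULL, discard = 25) {
  va <- .score_vec(a, dt); vb <- .score_vec(b, dt)
  stopifnot(length(va$v) == length(vb$v))
  keep <- seq_along(va$v) > round(discard / va$dt)
  x <- va$v[keep]; y <- vb$v[keep]
  1 - sum((x - y)^2) / sum((x - mean(x))^2)
}

.score_vec <- function(x, dt) {
  if (inherits(x, "ts_trace"))
    list(v = x$V_mV, dt = attr(x, "dt"))
  else {
    stopifnot(!is.null(dt))
    list(v = as.numeric(x), dt = dt)
  }
}

#' Energy dissipated in the emulated potassium channel
#'
#' Integrates \eqn{|V_K(t)|\,|i_K(t)|} over a window of a hybrid
#' simulation, in physical device units: \eqn{V_K = V_{scale}(v - E_K)}
#' volts and \eqn{i_K} the device current in uA. Two time conventions are
#' reported: biological (trace time, ms) and physical device time
#' (\code{dt/T_scale}); mean power is identical under both.
#'
#' @param trace hybrid trace from [simulate_hybrid()] (channels \code{V_mV},
#'   \code{w}).
#' @param mem a [memristor_params()] object.
#' @param s a [scaling_factors()] object.
#' @param E_K potassium reversal potential (mV).
#' @param t1,t2 integration window (ms); defaults to the whole trace.
#' @param law device law used in the simulation.
#' @param current_unit physical unit of the device current scales
#'   (\code{alpha}, \code{gamma}): \code{"nA"} (default) or \code{"uA"}.
#'   The hybrid dynamics are unit-free (the current scaling factor absorbs
#'   the device unit); only the energy accounting depends on it. The
#'   default follows the devices' nA-order operating currents, which is
#'   also the only reading under which spike-resolved and mean-power
#'   figures stay mutually consistent for these parameter sets.
#' @return List with \code{energy_uJ} (biological-time convention),
#'   \code{energy_uJ_phys} (device-time convention: physical hardware time
#'   runs \code{T_scale} times the model time), \code{duration_s},
#'   \code{mean_power_uW}.
#' @export
channel_energy <- function(trace, mem, s, E_K = -77, t1 = NULL, t2 = NULL,
                           law = c("sinh", "linear"),
                           current_unit = c("nA", "uA")) {
  law <- match.arg(law)
  current_unit <- match.arg(current_unit)
  keep <- .window_idx(trace, t1, t2)
  v <- trace$V_mV[keep]; w <- trace$w[keep]
  Vphys <- s$V_scale * (v - E_K)                       # volts
  iphys <- if (law == "linear") linear_variant_current(mem, w, Vphys)
           else device_current(mem, w, Vphys)          # device units
  i_to_uA <- if (current_unit == "nA") 1e-3 else 1
  p_uW <- abs(Vphys) * abs(iphys) * i_to_uA            # V * uA = uW
  dt_s <- attr(trace, "dt") * 1e-3
  e_bio <- .trapz(p_uW, dt_s)                          # uJ
  dur <- (length(keep) - 1) * dt_s
  list(energy_uJ = e_bio,
       energy_uJ_phys = e_bio * s$T_scale,
       duration_s = dur,
       mean_power_uW = e_bio / dur)
}

#' Energy dissipated in the full hybrid circuit
#'
#' Extends [channel_energy()] to the sum over the potassium (memristor),
#' sodium and leak elements, all expressed in the same physical unit
#' scaling: element voltages are \code{V_scale*(v - E_x)} volts, element
#' currents are membrane currents mapped through \code{I_scale} (the
#' memristor current is the device current itself).
#'
#' @inheritParams channel_energy
#' @param hh an [hh_params()] object.
#' @return List as in [channel_energy()] plus per-element mean powers
#'   \code{power_K_uW, power_Na_uW, power_L_uW}.
#' @export
circuit_energy <- function(trace, hh, mem, s, t1 = NULL, t2 = NULL,
                           law = c("sinh", "linear"),
                           current_unit = c("nA", "uA")) {
  law <- match.arg(law)
  current_unit <- match.arg(current_unit)
  keep <- .window_idx(trace, t1, t2)
  v <- trace$V_mV[keep]; w <- trace$w[keep]
  m <- trace$m[keep]; h <- trace$h[keep]
  dt_s <- attr(trace, "dt") * 1e-3
  dur <- (length(keep) - 1) * dt_s
  # potassium element: physical device voltage and current
  VK <- s$V_scale * (v - hh$E_K)
  iK <- if (law == "linear") linear_variant_current(mem, w, VK)
        else device_current(mem, w, VK)
  # sodium and leak elements in the same scaling as the memristor: the
  # membrane-unit K current is I_scale times the device current, so physical
  # element currents are membrane currents divided by I_scale
  VNa <- s$V_scale * (v - hh$E_Na)
  iNa <- hh$g_Na * m^3 * h * (v - hh$E_Na) / s$I_scale
  VL <- s$V_scale * (v - hh$E_L)
  iL <- hh$g_L * (v - hh$E_L) / s$I_scale
  i_to_uA <- if (current_unit == "nA") 1e-3 else 1
  pK <- abs(VK) * abs(iK) * i_to_uA
  pNa <- abs(VNa) * abs(iNa) * i_to_uA
  pL <- abs(VL) * abs(iL) * i_to_uA
  e_bio <- .trapz(pK + pNa + pL, dt_s)
  list(energy_uJ = e_bio,
       energy_uJ_phys = e_bio * s$T_scale,
       duration_s = dur,
       mean_power_uW = e_bio / dur,
       power_K_uW = .trapz(pK, dt_s) / dur,
       power_Na_uW = .trapz(pNa, dt_s) / dur,
       power_L_uW = .trapz(pL, dt_s) / dur)
}

.window_idx <- function(trace, t1, t2) {
  t <- trace$t_ms
  if (is.null(t1)) t1 <- t[1]
  if (is.null(t2)) t2 <- t[length(t)]
  which(t >= t1 & t <= t2)
}

.trapz <- function(y, dx) {
  n <- length(y)
  dx * (sum(y) - (y[1] + y[n]) / 2)
}

#' Energy report for a hybrid simulation
#'
#' Convenience wrapper combining channel and circuit energy accounting with
#' spike statistics.
#'
#' @inheritParams circuit_energy
#' @param threshold,refractory spike-detection settings.
#' @return An object of class \code{"energy_report"}.
#' @export
energy_report <- function(trace, hh, mem, s, t1 = NULL, t2 = NULL,
                          law = "sinh", threshold = -30, refractory = 2,
                          current_unit = "nA") {
  ek <- channel_energy(trace, mem, s, E_K = hh$E_K, t1 = t1, t2 = t2,
                       law = law, current_unit = current_unit)
  eh <- circuit_energy(trace, hh, mem, s, t1 = t1, t2 = t2, law = law,
                       current_unit = current_unit)
  keep <- .window_idx(trace, t1, t2)
  st <- detect_spikes(trace$V_mV[keep], dt = attr(trace, "dt"),
                      threshold = threshold, refractory = refractory)
  nspk <- length(st$times_ms)
  structure(list(
    E_K_uJ = ek$energy_uJ, E_HH_uJ = eh$energy_uJ,
    E_K_uJ_phys = ek$energy_uJ_phys, E_HH_uJ_phys = eh$energy_uJ_phys,
    duration_s = ek$duration_s,
    power_K_uW = ek$mean_power_uW, power_HH_uW = eh$mean_power_uW,
    n_spikes = nspk, rate_hz = spike_rate(st),
    energy_per_spike_K_nJ = if (nspk) 1000 * ek$energy_uJ / nspk else NA_real_,
    energy_per_spike_HH_nJ = if (nspk) 1000 * eh$energy_uJ / nspk else NA_real_),
    class = "energy_report")
}

#' @export
print.energy_report <- function(x, ...) {
  cat(sprintf("Energy report over %.3f s (biological time)\n", x$duration_s))
  cat(sprintf("  K channel:  %.3g uJ (%.3g uW mean)\n", x$E_K_uJ, x$power_K_uW))
  cat(sprintf("  full circuit: %.3g uJ (%.3g uW mean)\n",
              x$E_HH_uJ, x$power_HH_uW))
  cat(sprintf("  %d spikes (%.1f Hz): %.3g nJ/spike (K), %.3g nJ/spike (HH)\n",
              x$n_spikes, x$rate_hz, x$energy_per_spike_K_nJ,
              x$energy_per_spike_HH_nJ))
  invisible(x)
}

#' Whole-brain power extrapolation
#'
#' Coarse extrapolation of a per-neuron power figure to the 86 billion
#' neurons of a human brain.
#'
#' @param power_per_neuron_w mean power per neuron (W).
#' @param n_neurons neuron count.
#' @return Power in kW.
#' @export
brain_extrapolation <- function(power_per_neuron_w, n_neurons = 8.6e10) {
  stopifnot(power_per_neuron_w >= 0, n_neurons >= 0)
  power_per_neuron_w * n_neurons / 1000
}
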