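#' Multi-compartment axon configuration
#'
#' A chain of identical hybrid compartments with resistive nearest-neighbour
#' coupling and sealed ends; the stimulus is injected into one compartment.
#'
#' @param n_compartments number of compartments (>= 2).
#' @param g_axial coupling conductance between neighbours (mS/cm^2). The
#'   default sits in the middle of the propagation-success region for the
#'   NbOx-tuned chain.
#' @param target 1-based index of the stimulated compartment.
#' @return An object of class \code{"axon_config"}.
#' @export
axon_config <- function(n_compartments = 30, g_axial = 1, target = 1) {
  stopifnot(n_compartments >= 2, g_axial > 0,
            target >= 1, target <= n_compartments)
  structure(list(n_compartments = n_compartments, g_axial = g_axial,
                 target = target), class = "axon_config")
}

#' Simulate the hybrid axon
#'
#' Each compartment evolves by the hybrid membrane ODE plus
#' \code{g_axial * (V_neighbour - V_self)} coupling currents (sealed ends:
#' boundary compartments have a single neighbour).
#'
#' @param cfg an [axon_config()].
#' @param hh,mem,s model parameters as in [simulate_hybrid()].
#' @param stimulus applied current for the target compartment.
#' @param dt integration step (ms).
#' @param law device law, \code{"sinh"} or \code{"linear"}.
#' @param keep_every store every k-th sample of the voltage matrix.
#' @return A [ts_trace()] with one voltage channel per compartment
#'   (\code{V1 ... Vn}, mV), sampled at \code{dt * keep_every}.
#' @export
simulate_axon <- function(cfg, hh, mem, s, stimulus, dt = 0.005,
                          law = c("sinh", "linear"), keep_every = 10) {
  stopifnot(inherits(cfg, "axon_config"), inherits(hh, "hh_params"),
            inherits(mem, "memristor_params"), inherits(s, "scaling_factors"))
  law <- match.arg(law)
  iapp <- .stimulus_vector(stimulus, dt)
  g <- gate_steady(-60)
  m <- cpp_axon_sim(.hh_vec(hh), .mp_vec(mem),
                    s$V_scale, s$T_scale, s$I_scale, iapp, dt,
                    cfg$n_compartments, cfg$g_axial, cfg$target - 1L,
                    -60, g$m_inf, g$h_inf, mem$w_min,
                    law == "linear", as.integer(keep_every))
  df <- as.data.frame(m)
  names(df) <- paste0("V", seq_len(cfg$n_compartments))
  ts_trace(df, dt = dt * keep_every)
}

#' Spike-wave propagation metrics
#'
#' Quantifies whether a spike wave launched at the stimulated compartment
#' reaches the far end: per-compartment first threshold-crossing times and a
#' propagation flag.
#'
#' @param trace axon voltage trace from [simulate_axon()].
#' @param threshold spike threshold (mV).
#' @param window maximum allowed delay (ms) between the first compartment's
#'   crossing and every other compartment's crossing.
#' @return List with \code{propagated} (logical), \code{first_cross_ms}
#'   (per-compartment first crossing times, NA if never) and
#'   \code{delay_ms} (crossing time relative to the first compartment).
#' @export
propagation_metrics <- function(trace, threshold = -30, window = 50) {
  vcols <- grep("^V", names(trace), value = TRUE)
  dt <- attr(trace, "dt")
  first_cross <- vapply(vcols, function(cn) {
    k <- which(trace[[cn]] > threshold)[1]
    if (is.na(k)) NA_real_ else trace$t_ms[k]
  }, numeric(1))
  delays <- first_cross - first_cross[1]
  propagated <- !anyNA(first_cross) &&
    all(delays[-1] >= 0) && all(delays <= window)
  list(propagated = isTRUE(propagated), first_cross_ms = first_cross,
       delay_ms = delays)
}

#' Frequency-current curve
#'
#' Firing rate under a constant-current step for a grid of amplitudes, for
#' either the reference HH neuron or the hybrid neuron. Shows the
#' all-or-nothing behaviour: zero rate below rheobase, non-decreasing above.
#'
#' @param currents amplitudes to sweep (uA/cm^2).
#' @param model \code{"hh"} or \code{"hybrid"}.
#' @param hh,mem,s parameters (\code{mem}, \code{s} required for
#'   \code{"hybrid"}).
#' @param duration step duration (ms); an initial transient is discarded
#'   before counting.
#' @param dt integration step (ms).
#' @param law device law for the hybrid model.
#' @param discard transient discarded before counting spikes (ms).
#' @param threshold,refractory spike-detection settings.
#' @return data.frame with columns \code{i_app} and \code{rate_hz}.
#' @export
fi_curve <- function(currents, model = c("hh", "hybrid"), hh = hh_params(),
                     mem = NULL, s = NULL, duration = 500, dt = 0.005,
                     law = "sinh", discard = 50,
                     threshold = -30, refractory = 2) {
  model <- match.arg(model)
  rates <- vapply(currents, function(i0) {
    stim <- rep(i0, round(duration / dt))
    tr <- if (model == "hh") simulate_hh(hh, stim, dt)
          else simulate_hybrid(hh, mem, s, stim, dt, law = law)
    keep <- tr$t_ms >= discard
    st <- detect_spikes(tr$V_mV[keep], dt = dt, threshold = threshold,
                        refractory = refractory)
    1000 * length(st$times_ms) / (duration - discard)
  }, numeric(1))
  data.frame(i_app = currents, rate_hz = rates)
}
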