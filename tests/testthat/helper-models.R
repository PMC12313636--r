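# shared fixtures: canonical parameter sets and small simulation helpers
hh0 <- hh_params()
nbox <- device_preset("nbox")
wox <- device_preset("wox")
s_nbox <- scaling_preset("nbox")
s_wox <- scaling_preset("wox")

# constant-current stimulus vector of `ms` milliseconds
const_stim <- function(i0, ms, dt = 0.005) rep(i0, round(ms / dt))

# reference arithmetic for the device law, written out independently of the
# package's vectorised implementation
ref_device_current <- function(p, w, V) {
  (1 - w) * p$alpha * (1 - exp(-p$beta * V)) + w * p$gamma * sinh(p$delta * V)
}
ref_state_rate <- function(p, w, V) {
  (1 - exp(w - 3)) * p$lam * sinh(p$eta * V) - (w - p$w_min) / p$tau
}
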