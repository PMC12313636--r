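---
title: "Emulating the Hodgkin-Huxley potassium channel with a volatile memristor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Emulating the Hodgkin-Huxley potassium channel with a volatile memristor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memhh)
```

## The model

Voltage-gated ion channels are memristors in Chua's sense: two-terminal
elements whose conductance depends on the history of the applied signal,
with a pinched hysteresis loop under oscillatory bias. `memhh` implements a
compact model of volatile oxygen-vacancy memristors (niobium-oxide and
tungsten-oxide devices) and the machinery to ask, quantitatively, whether
such a device can stand in for the potassium channel of the classic
squid-axon conductance model.

The device law has two parallel conduction paths modulated by a single
internal state $w \in [w_{min}, w_{max}]$, which tracks the oxygen-vacancy
configuration at the interface:

$$i(w, V) = (1-w)\,\alpha\,(1 - e^{-\beta V}) + w\,\gamma \sinh(\delta V)$$

$$\dot w = W(w)\,\lambda \sinh(\eta V) - \frac{w - w_{min}}{\tau},
\qquad W(w) = 1 - e^{w-3}$$

The first current term is a Schottky barrier, the second tunneling; bias
drives $w$ up at a sinh-shaped rate while it relaxes back to $w_{min}$ with
time constant $\tau$ when unbiased (volatility). The window $W$ gates the
potentiation term only; the decay is plain first-order relaxation. We treat
the bracket placement that would put the window on the whole right-hand
side as typographical: applying it to the decay as well would leave the
state equation without a guaranteed fixed point at $w_{min}$ and disagrees
with the source device model this law descends from.

Ignoring the window, the steady state
$w_\infty = w_{min} + \tau\lambda\sinh(\eta V)$ (clipped to the bounds) is
sigmoidal in $V$, and the relaxation time falls from $\tau$ at weak drive
to $1/(\lambda\sinh(\eta V))$ at strong drive — the same qualitative
structure as the potassium activation gate $n$, whose steady state is a
sigmoid and whose time constant is voltage-dependent. Expanding $i$ around
$V = 0$ gives $i \approx w(\gamma\delta - \alpha\beta)V + \alpha\beta V$: a
conductance linear in the state plus a persistent Schottky leak. These
three analytic properties (`steady_state_w()`,
`effective_time_constant()`, `linearized_current()`) are what make the
device a candidate potassium channel, and they are tested as such.

Two parameter presets ship with the package (`device_preset()`). The
tungsten-oxide decay constant is 50 ms: the table this preset descends from
prints its unit inconsistently, and every statement about that device (an
order of magnitude slower than the niobium device, matching biology when
its decay is shortened five-fold) requires 50 ms, so that value is used.

## The hybrid neuron

The reference neuron is the canonical squid-axon model in the modern
convention ($C_m = 1\,\mu F/cm^2$, $g_{Na} = 120$, $g_K = 36$,
$g_L = 0.3\; mS/cm^2$, $E_{Na} = +50$, $E_K = -77$, $E_L = -54.4$ mV),
chosen because the study conditions use "default units" and an initial
voltage of $-60$ mV, both consistent with this set; all values are
overridable. In the hybrid neuron (`simulate_hybrid()`) the potassium
branch $g_K n^4 (V - E_K)$ is deleted and replaced by the memristor,
bridged by three scaling factors:

$$i_K = I_{scale}\, i\!\left(w,\; V_{scale}(v - E_K)\right), \qquad
\dot w = T_{scale} \cdot \left[\text{device law at } V_{scale}(v -
E_K)\right]$$

$V_{scale}$ maps millivolt-order membrane excursions onto the volt-order
biases the device needs, $T_{scale}$ re-times the device, and $I_{scale}$
maps device current onto membrane current density. The Schottky exponent is
driven by the same $V_{scale}(v-E_K)$ as the tunneling term; the
small-signal expansion of the device law is taken around $v = E_K$, which
fixes that reading. Scaling the equations is equivalent to re-scaling the
passive components of a physical circuit; `scale_passive()` returns the
implied component values, and the test suite verifies that a from-scratch
simulation of the physically scaled circuit reproduces the unit-space
trajectory to $10^{-9}$ relative. That equivalence — not any printed
formula — is the definition we use for the scaled capacitance
($C'_m = T_{scale} C_m / (V_{scale} I_{scale})$), since the source
expression is typographically ambiguous.

All neuron simulations use Euler–Maruyama at $dt = 0.005$ ms from
$V(0) = -60$ mV, $w(0) = w_{min}$, with gates at their voltage steady
state. The stimulus is an Ornstein–Uhlenbeck current
($dX = -\theta X dt + \sigma dW$, $\theta = 0.1$/ms, $\sigma = 0.7$,
output gain 4), the "(nA)" tag on the published stimulus being read as a
units slip for current density. A divergence guard aborts a hybrid
simulation if $|V|$ exceeds 500 mV — far outside physiology, reached only
for pathological scale candidates. sinh/exp arguments are clamped at
magnitude 40; such biases are unphysical for these devices.

## Calibration

**Stage 1 (reduced model).** A fixed-voltage potentiation/decay experiment
collapses the device law to
$\dot G = -(G - G_{min})/\tau + A\cdot[\text{pulse on}]$.
`fit_reduced()` recovers $(\tau, A, G_{min})$ by minimising the MSE of the
unrolled forward-Euler simulation. Gradients are central finite differences
in log-parameter space fed to Adam (an L-BFGS-B option converges much
faster on clean data); the contract is parameter recovery, not the
gradient mechanism.

**Stage 2 (full model).** With $\tau$ fixed, `fit_full()` recovers the
remaining seven constants from a varying-voltage pulse sweep, under the
soft constraints of `constraint_loss()`: a $w_{min}$ anchor at 0.15
(weight $10^3$), a trajectory overshoot penalty $\sum w H(w-1)$ (weight
$10^2$), non-negativity barriers (weight $10^4$) on
$\alpha, \beta, \gamma, w_{min}, \lambda, \eta$, a $\beta$ anchor at 0.5
(weight 1), and a squared residual tying the baseline read current to the
stage-1 conductance (weight $10^2$; no published weight exists for this
equality, so it is configurable). The data term is the *sum* of squared
current errors: with a per-sample mean, the fixed-weight anchors dominate
and drag the optimum to $w_{min} \approx 0.15$ with $\gamma$ biased ~30%
low — whereas the reference calibration this mirrors demonstrably had a
data term strong enough to pull $w_{min}$ to 0.117 against its anchor
while $\beta$ stayed anchor-held near 0.5 and $\alpha$ remained
unidentifiable. The SSE reading reproduces exactly those signatures on
synthetic data (sub-1% recovery of $\gamma, \delta, \eta, \lambda$;
$\beta$ pinned; $\alpha$ loose). During the unrolled simulation $w$ is
clipped to $[w_{min}, 0.99]$ to prevent forward-Euler overshoot.

**Synthetic experiments.** `generate_potentiation_decay()` and
`generate_pulse_sweep()` produce the characterisation data the two stages
consume: write pulses of 10 ms at 4 V (stage 1) or swept over 1–4 V
(stage 2), 50 ms inter-pulse decay, 10 pulses, sampled at 0.05 ms, with
optional multiplicative Gaussian measurement noise (default 1% where
noise is requested). The exact pulse geometry of the original bench
experiments is not published; these defaults make both potentiation and
decay clearly visible at $\tau \approx 12$ ms and are configurable. The
sweep records the current at the applied bias (write level during pulses,
0.7 V read level in between, with reads treated as non-perturbing): read
currents at a single fixed voltage constrain only the product
$\gamma\sinh(0.7\,\delta)$, so sampling across the sweep voltages is what
makes $\gamma$ and $\delta$ separately identifiable. The generators are
pure functions of their parameters and seed. They emulate the *model's*
own statistics plus measurement noise; they do not emulate real-device
non-idealities (cycle-to-cycle drift, read disturb, quantisation), so
passing recovery tests demonstrates correctness of the fitting machinery,
not robustness to every bench artefact.

**Scaling search.** `fit_scaling()` searches
$(V_{scale}, T_{scale}, I_{scale})$ over $[10^{-3}, 10^3]$ by CMA-ES,
minimising the MSE between hybrid and reference voltage traces (common
stimulus realization) after discarding the first 25 ms transient; the
six-decade positive range motivates searching in $\log_{10}$ space with an
initial step of one decade. No CMA-ES implementation was available as a
dependency, so the package carries a compact standard
$(\mu/\mu_w, \lambda)$ implementation (`cma_es()`) with rank-one/rank-mu
updates and cumulative step-size adaptation. The score surface is
treacherous: a correlated valley of near-optimal scale combinations, and a
very narrow funnel around any exactly matching configuration, because a
small scale mismatch shifts spike times and the MSE jumps by orders of
magnitude. The search therefore combines a seeded log-uniform presample
with restarts (best incumbent kept, optional early stop once a
numerical-match score is reached). Recovering a known configuration is
reliable with a dozen restarts; a single run succeeds only a minority of
the time. The default fitting horizon is 300 ms (about a dozen reference
spikes — long enough to score co-timing, short enough to keep a search in
the tens of seconds); `evaluate_r2()` scores a five-fold longer horizon.

## Energy accounting

`channel_energy()` integrates $|V_K||i_K|$ over a window, with
$V_K = V_{scale}(v - E_K)$ in volts and $i_K$ the device current;
`circuit_energy()` adds the sodium and leak branches in the same unit
scaling (element voltages $V_{scale}(v - E_x)$; physical element currents
are membrane currents divided by $I_{scale}$, since the membrane-unit
potassium current is $I_{scale}$ times the device current). Absolute
values are deliberate: the accounting tracks dissipation magnitude, not
signed power flow.

Two conventions are reported and one judgement call is documented:

* **Time base.** Energies integrate over the biological (trace) time;
  the device-hardware time base (`T_scale` times slower or faster)
  is reported alongside (`energy_uJ_phys`). The per-spike and mean-power
  figures quoted in the reference work are mutually consistent only under
  the biological convention, so that is the headline.
* **Current unit.** The hybrid dynamics are invariant to the physical
  unit of $\alpha$ and $\gamma$ (the current scaling factor absorbs it),
  but energy is not. With these presets read as microamps, the quiescent
  device alone would dissipate several microwatts and a single spike
  microjoules — orders of magnitude above every published figure for this
  device class, whose spike-resolved energies are nanojoules. Read as
  nanoamps the accounting is self-consistent, so `current_unit = "nA"` is
  the default and `"uA"` is available.

## The axon and rate analyses

`simulate_axon()` chains hybrid compartments with resistive
nearest-neighbour coupling (sealed ends), stimulus into compartment 1.
The coupling conductance is not published; a one-dimensional sweep showed
spike waves propagating end-to-end for $g_{axial}$ roughly between 0.3 and
1.5 mS/cm² on the niobium-tuned chain (failing below by decay and above by
loading), so the default sits at 1 mS/cm², the middle of that region.
`propagation_metrics()` reduces an axon trace to first-crossing times and
a propagation flag; `fi_curve()` sweeps constant currents for the
all-or-nothing rate curve. Spike detection (`detect_spikes()`) uses upward
crossings of $-30$ mV with a 2 ms refractory — low enough to catch the
reduced-height hybrid spikes, high enough to reject subthreshold
fluctuations; both are configurable.

## Known limitations

* At the published scale factors the hybrid neuron reproduces the
  potassium current well across the subthreshold range (verified
  open-loop by driving the scaled device with the reference voltage
  trajectory), but closed-loop the sinh tunneling term surges during the
  upstroke and the slowly decaying state vetoes a fraction of
  would-be spikes. Spike peaks sit roughly half the reference height
  above rest and the full-spike rate is well below the reference
  neuron's; counting subthreshold initiation events as well brings the
  event rate much closer. The linear-conductance variant
  (`law = "linear"`) restores spike height, confirming the sinh term as
  the cause.
* The scaling-search optimum is a degenerate valley; different search
  seeds (and different implementations) legitimately return different
  members of it. Voltage scale is the best-pinned factor.
* The generators emulate the model's statistics, not bench non-idealities;
  device-to-device variability is out of scope.
* Forward Euler at 0.005 ms is the study condition, not a recommendation;
  halving the step changes trajectories by well under 1% (tested), but
  stiff parameter regions outside the presets may need smaller steps.

## A short session

```{r example, eval = FALSE}
hh  <- hh_params()
mem <- device_preset("nbox")
s   <- scaling_preset("nbox")

stim <- ou_process(1000, seed = 1)      # 1 s of OU drive
gt   <- simulate_hh(hh, stim)
hy   <- simulate_hybrid(hh, mem, s, stim)

spike_height_reduction(gt, hy)
energy_report(hy, hh, mem, s)

fs <- fit_scaling(simulate_hh(hh, ou_process(300, seed = 1)),
                  hh, mem, ou_process(300, seed = 1), seed = 2)
coef(fs)
```
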