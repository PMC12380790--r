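---
title: "A thalamo-cortical spiking network model of deep brain stimulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A thalamo-cortical spiking network model of deep brain stimulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(tcmdbs)
```

## The model

`tcmdbs` simulates a thalamo-cortical microcircuit of 540 spiking neurons
in six populations: three excitatory cortical layers — supragranular (S,
100 neurons), middle (M, 100) and deep (D, 100) — a shared pool of
cortical interneurons (CI, 100), and the two thalamic populations, the
excitatory thalamocortical relay nucleus (TCR, 100) and the inhibitory
thalamic reticular nucleus (TRN, 40). Structures are indexed j = 1..6 in
the order S, M, D, CI, TRN, TCR.

Each neuron i of structure j follows Izhikevich dynamics,

$$\dot v_{ij} = 0.04\,v_{ij}^2 + 5 v_{ij} - u_{ij} + 140 + I_{ij},
\qquad \dot u_{ij} = a_{ij}(b_{ij} v_{ij} - u_{ij}),$$

with the reset rule: when $v_{ij} \ge v_p + \zeta(t)$ the neuron emits a
spike, $v_{ij} \to c_{ij}$ and $u_{ij} \to u_{ij} + d_{ij}$. The total
current $I_{ij}$ sums a constant bias, the delayed synaptic input, an
optional Poissonian background term, Gaussian membrane noise $\xi(t)$,
and — for layer D only — the DBS current $I_{\mathrm{dbs}}$. The spiking
threshold is itself perturbed per neuron per step by Gaussian noise
$\zeta(t)$ (sd 0.1 mV by default); we perturb the threshold side of the
comparison, exactly as the reset condition is written.

Synapses follow the Tsodyks–Markram short-term plasticity model. Each
presynaptic neuron carries three synapse classes — facilitating (F),
depressing (D) and pseudo-linear (P) — with state $(u, x, I)$:
utilization $u$ decays to 0 with $\tau_f$, resources $x$ recover to 1
with $\tau_d$, and the postsynaptic current $I$ decays with $\tau_s$.
An arriving spike applies, in the standard order,
$u^+ = u^- + U(1-u^-)$, $\Delta I = A\,u^+ x^-$, $x^+ = x^- - u^+ x^-$.
Class fractions per projection mix the three PSCs, and a dense
(all-to-all, no self-loops) weight matrix delivers them to the target
population after the projection's conduction delay.

The periodic steady state of this synapse under presynaptic rate $r$
(period $T = 1000/r$ ms) has the closed form

$$u_{ss} = \frac{U}{1-(1-U)e^{-T/\tau_f}},\qquad
x_{ss} = \frac{1-e^{-T/\tau_d}}{1-(1-u_{ss})e^{-T/\tau_d}},$$

with steady PSC jump $A\,u_{ss} x_{ss}$ (`tm_steady_state()`). For
depressing parameters this amplitude falls monotonically with rate —
at the default depressing class, the 130 Hz amplitude is about 17% of
the 20 Hz amplitude. This *synaptic suppression* is the mechanism by
which high-frequency DBS throttles the stimulated layer's output.

## What a simulation computes

One step of `simulate()` executes, in a fixed documented order: read the
delay-shifted presynaptic PSCs and aggregate them through the weight
matrices; add bias, background and DBS currents; Euler-step all neurons
with membrane noise and detect spikes against the noisy threshold; relax
all synapse states and apply this step's spike jumps; push the new PSC
values into per-projection circular delay buffers. Delays act at
delivery: a spike at step $s$ first affects its targets at step
$s + \Delta$ (minimum one step).

Three engines implement the identical algorithm: a compiled vectorized
loop (the default), a vectorized pure-R loop built from the exported
module operations, and a deliberately naive scalar reference with
explicit per-neuron and per-synapse loops. The compiled engine orders
its floating-point accumulations exactly as the scalar reference
(ascending source index within each projection, projections visited in a
fixed order), so the two agree *bit for bit* — the test suite asserts
identical spike records over $10^4$ steps, with and without shared noise
draws. The pure-R engine delegates its matrix-vector products to BLAS,
whose summation order differs in the last ulp; it is checked exactly
over shorter horizons.

## Parameters and defaults

Every parameter is configurable through a YAML schema
(`default_config()`, `save_config()`, `load_config()`, all validated by
`validate_config()`). Units are mV, ms, and Izhikevich's dimensionless
current scale.

* **Neuron archetypes** (placeholders in the canonical Izhikevich
  parameterization): regular spiking (a=0.02, b=0.2, c=−65, d=8) for
  S/M/D/TCR, fast spiking (a=0.1, b=0.2, c=−65, d=2) for CI,
  low-threshold spiking (a=0.02, b=0.25, c=−65, d=2) for TRN;
  $v_p$ = 30 mV. Heterogeneity follows the canonical randomization:
  excitatory cells perturb $(c, d)$ by $15r^2$ and $-6r^2$; inhibitory
  cells perturb $(a, b)$ along the FS–LTS continuum, directed away from
  the archetype's end of the range so values stay canonical.
* **Synapse classes**: canonical F/D/P triplets per source type
  (excitatory: U = 0.09/0.5/0.29 with the facilitating class having
  $\tau_f > \tau_d$; inhibitory: the canonical inhibitory triplets);
  $\tau_s$ = 3 ms (excitatory) and 11 ms (inhibitory). The connection
  sign is applied exactly once, through the weight matrix; `A` is
  validated with the sign of its source type but only its magnitude
  scales the PSC jump (applying the sign in both places would cancel).
* **Delays**: 1 ms within cortex and within thalamus, 8 ms between
  them, rounded to integer steps (warning above 10% rounding error).
* **Noise**: membrane noise sd 0.5, threshold noise sd 0.1, Poissonian
  background disabled — the reference protocol. Two membrane-noise
  conventions are exposed: `per_step` adds N(0, σ) once per step (the
  convention in which the noise term is *not* multiplied by the time
  step), and `sqrt_dt` adds $\sigma\sqrt{dt}\,$N(0,1), the
  stochastic-Euler form whose ensemble variance grows as $\sigma^2 t$
  independently of dt. The default is `sqrt_dt` because it makes results
  dt-robust; the two coincide at dt = 1 ms, and the suite verifies the
  $\sigma^2 t$ law against 1000-replicate ensembles.
* **DBS**: monophasic rectangular pulses (a charge-balanced biphasic
  option exists), default width 0.3 ms, amplitude 120, 130 Hz, onset 6 s,
  injected into every D neuron and nowhere else. Width, shape and
  amplitude are tuning constants of this package.
* **Integration**: explicit Euler, dt = 0.1 ms. The quadratic membrane
  term can make Euler unstable at large steps; `validate_config()` warns
  above 0.5 ms.

### Where the default gains come from

The per-projection gain magnitudes are deliberately *tuned constants*:
strong recurrent excitation among S/M/D (gain 10, normalized by source
size), cortical drive onto CI (8) with inhibitory feedback (−8), and a
weaker thalamic loop (D→TCR 3, TCR→cortex 3, TRN→TCR −6, delays 8 ms).
Bias currents sit just below the RS rheobase (3.9 vs 4.0) so firing is
noise-driven. These values place the unstimulated network in a
parkinsonian-like state: recurrent excitation ignites population bursts,
interneuron feedback and spike-frequency adaptation terminate them, and
the result is synchronized bursting (mean cortical Golomb–Hansel
synchrony ≈ 0.5) with clearly elevated beta-band power relative to an
asynchronous network. The burst fundamental sits at ~8.5 Hz — set by the
canonical RS adaptation time constant (1/a = 50 ms, d = 8) — with
strong harmonics through the 13–30 Hz band; shifting the fundamental
itself into beta would require neuron parameters outside the canonical
archetypes, which we deliberately keep. All gains are overridable.

## Quantifying the DBS contrast

The analysis layer operationalizes "synchronized activity" and "beta
power", which a raster only shows qualitatively:

* `spike_signals()` bins each neuron's train at 1 ms and smooths with a
  5 ms Gaussian kernel; `synchrony_index()` computes the Golomb–Hansel
  coherence $\chi = \sqrt{\mathrm{Var}_t[\bar s(t)] / \overline{\mathrm{Var}_t[s_i(t)]}}$
  — 1 for identical signals, →0 for independent ones as N grows, and
  invariant to amplitude scaling.
* `lfp_proxy()` uses the mean-subtracted 1 ms-binned population spike
  count (or the recorded population-mean voltage) as an LFP surrogate;
  `band_power()` estimates its spectrum by Welch averaging (2 s Hann
  windows, 50% overlap) and integrates 13–30 Hz.
* `compare_epochs()` evaluates both per structure over a pre-DBS epoch
  (1 s to onset) and a DBS epoch (onset + 1 s to the end); the first
  second of each epoch is excluded as a settle-in margin.

With the default 12 s protocol (DBS from second 6 into layer D),
averaged over five paired seeds and the four cortical structures, the
package's acceptance script reproduces the characteristic contrast:
130 Hz stimulation drives D into high-rate tonic firing whose output is
suppressed by synaptic depression, breaking the burst rhythm — cortical
$\chi$ falls to ≈ 1/3 of its pre-DBS value and beta power to ≈ 10% —
whereas 20 Hz stimulation entrains the network pulse by pulse, keeping
$\chi$ near its pre-DBS level and *raising* beta power (the resonance
of low-frequency stimulation). Exact numbers for a given seed are
written by `scripts/acceptance.R` and by `reproduce_dbs_contrast()`.

```{r contrast}
out <- reproduce_dbs_contrast("dbs_out", seeds = 1:5)
out$summary
```

## Numerical choices

* Exponential (exact) relaxation for the TM states each step, rather
  than Euler decay: unconditionally stable and analytically testable.
* TM states are flushed to their no-activity fixed point once within
  1e-12 of it (u → 0, x → 1, I → 0). Twelve orders of magnitude below a
  single PSC jump this is physically nil, and it prevents the
  exponential tails of silent synapses from drifting into subnormal
  floating-point numbers, whose arithmetic is an order of magnitude
  slower. The rule is identical in all three engines.
* One TM state per presynaptic neuron and class, with per-pair weights
  applied at aggregation — this keeps the 540-neuron all-to-all network
  tractable while preserving per-source-neuron PSC resolution.
* RNG discipline: the master seed is split into named substreams
  (weights, heterogeneity, membrane, threshold, background), so enabling
  or disabling one noise source does not shift the draws of another in
  the compiled engine. Results are deterministic per engine and seed;
  the R engines additionally accept explicit noise matrices, which is
  how the cross-engine equivalence tests share draws.
* Spike times are recorded at the end of the step in which the
  threshold crossing is detected; the recorded voltage for that step is
  clamped to $v_p$, the standard convention for this neuron model.
* Initial conditions: $v_0 = c$ (post-heterogeneity), $u_0 = b v_0$.
  With zero bias and zero noise every default neuron starts at or below
  the saddle point of its membrane equation, so the network is provably
  silent — the degenerate-input tests assert this over a full run.

## What the simulations do and do not show

The generator emulates the *network states* of interest — synchronized
bursting with elevated beta power, its entrainment by low-frequency
stimulation, and its dissolution under high-frequency stimulation via
synaptic suppression — under documented stand-in parameters for
quantities the underlying model family defers to companion parameter
tables (per-population neuron constants, exact gain magnitudes, DBS
pulse shape). Passing tests therefore demonstrate the mechanisms and
their direction, not quantitative agreement with any particular
experimental recording. Known limitations: no spatial geometry or
electric-field model of the stimulation source (the DBS current is
injected intracellularly and identically into every D neuron), no
long-term plasticity, no suprathreshold naturalistic thalamic input,
and a burst fundamental below the beta band as discussed above.
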