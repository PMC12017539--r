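---
title: "A laminar spiking column model and its perturbation analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A laminar spiking column model and its perturbation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

`colspike` simulates a cortical column of primary visual cortex as a network
of leaky integrate-and-fire (LIF) point neurons organised into 17 cell
groups: VIP interneurons in layer 1, and pyramidal (E), PV, SST and VIP
cells in each of layers 2/3, 4, 5 and 6. Each complete layer is 85%
pyramidal and 15% interneurons. Every group carries its own
electrophysiology: resting potential $V_{rest}$, threshold $V_{th}$,
capacitance $C_m$ (pF), leak conductance $g_L$ (nS) and refractory period
$\tau_{ref}$ (ms), with membrane time constant $\tau_m = C_m/g_L$.

The membrane obeys

$$C_m \frac{dV}{dt} = -g_L\,(V - V_{rest}) + I_{syn}(t),$$

with threshold crossing emitting a spike, instantaneous reset to
$V_{rest}$, and a clamp at $V_{rest}$ for $\tau_{ref}$ during which inputs
cannot move the membrane.

## Synaptic currents

The total current decomposes into an external DC term (stimulation
protocols), background AMPA drive, and recurrent AMPA, NMDA and GABA-A
components:

$$I_{syn} = I_{ext} + I_{bg,AMPA} + I_{AMPA} + I_{NMDA} + I_{GABA}.$$

Each receptor current is a conductance times a driving force,
$g \cdot s \cdot (V_{rev} - V)$, with $V_E = 0$ mV for the glutamatergic
channels and the *neuron's own* $V_{rest}$ serving as the inhibitory
reversal. Two conventions deserve note:

* **Sign convention.** Currents are written with the driving force
  $(V_{rev}-V)$ so that AMPA/NMDA input depolarises any neuron below 0 mV
  and GABA pulls toward rest (shunting above rest). Writing the driving
  force the other way round while adding the current with a positive sign
  would make excitation hyperpolarising, contradicting the model's
  behaviour, so this orientation is the only self-consistent one.
* **Inhibitory reversal.** A reversal potential is a property of the
  postsynaptic channel, so `colspike` uses the postsynaptic neuron's own
  $V_{rest}$ as $V_I$. The alternative reading (the presynaptic group's
  rest value) would require per-projection reversals and is not adopted.

The NMDA current carries the voltage-dependent magnesium block

$$f(V) = \frac{1}{1 + [\mathrm{Mg}^{2+}]\,e^{-0.062 V}/3.57},$$

which is 1 in the magnesium-free limit and strictly increasing in $V$
($[\mathrm{Mg}^{2+}] = 1$ mM by default, $f(0) \approx 0.781$).

Gating dynamics: AMPA and GABA accumulators decay with $\tau_{AMPA} = 2$ ms
and $\tau_{GABA} = 5$ ms and jump by the synaptic weight on each
presynaptic spike. NMDA gating is second order: an auxiliary variable $x$
(rise constant 2 ms) accumulates weighted spikes, and the channel fraction
$s \in [0,1]$ follows
$\dot s = -s/\tau_{decay} + \alpha x (1 - s)$ with $\tau_{decay} = 80$ ms
and $\alpha = 0.5\,\mathrm{ms}^{-1}$; the $(1-s)$ factor saturates the
channel. The NMDA pair is aggregated per *postsynaptic* neuron (weighted
deliveries accumulate in $x$), a standard reduction of the per-synapse
formulation that keeps the state linear in network size; its practical
consequence is that NMDA saturation acts at the whole-neuron level rather
than per contact, which is immaterial in the low-rate regimes simulated
here but would compress strong per-synapse heterogeneity.

## Connectivity and weights

Networks are built from three 17×17 group-level matrices: connection
probabilities $P$ (289 entries), synaptic strengths $S$ in mV (288 defined
entries — the layer-1 self-projection is undefined and treated as absent)
and Gaussian lateral widths $\sigma$ in µm. Two transformations connect
the matrices to realized synapses:

* **Disk-uniform probability correction.** Probabilities measured over a
  reference column of radius $R_0 = 75$ µm under a Gaussian lateral profile
  $A e^{-r^2/\sigma^2}$ are translated to the uniform probability over the
  simulated column of radius $R = 125$ µm:
  $$P_{new} = P_{rep}\,\frac{R_0^2}{R^2}\,
    \frac{1 - e^{-R^2/\sigma^2}}{1 - e^{-R_0^2/\sigma^2}}.$$
  The printed form of the amplitude $A$ in the source material is
  typographically garbled; this closed form is the unique reading that
  reproduces both limits (flat profiles leave $P_{rep}$ unchanged; narrow
  profiles approach $P_{rep} R_0^2/R^2 = 0.36\,P_{rep}$ at these radii),
  and the implementation is property-tested against both.
* **Size-invariant weights.** Every realized synapse between two groups
  carries $w = G\,w_s/(N_{send}\,p)$ with global coupling
  $G = 5\,\mathrm{mV}^{-1}$, so the expected summed weight onto a target
  from any source group is exactly $G\,w_s$ regardless of network size.
  The $p$ in this formula is the corrected probability actually used to
  realize the projection — the only choice under which the invariance is
  exact.

Excitatory projections split over receptor channels: AMPA contacts are
drawn with $0.8\,p$ and NMDA contacts independently with $0.2\,p$
(independence across the two channels is assumed; the alternative, coupled
draws, would only change the overlap statistics of the two contact sets,
which nothing downstream consumes). Inhibitory projections are drawn once
for GABA. Draws are Bernoulli per ordered pair, without autapses, with at
most one synapse per (pre, post, receptor) triple.

Two structural variants are available: lognormally distributed individual
weights (per-projection arithmetic mean and SD both equal to the uniform
weight, i.e. $\sigma_{\log}^2 = \ln 2$), and an inhibitory-output lesion
removing every GABA synapse while interneurons keep receiving input and
spiking.

## Background drive and stimulation

Every neuron owns a private homogeneous Poisson generator feeding its
background AMPA channel at a group-specific rate $\nu_{bg}$, with unit
weight per event (no background weight is specified by the design the
package follows; unity is the natural convention when the background
conductance scale is absorbed into $\nu_{bg}$). State protocols inject DC
currents: the feedforward state drives 25% of E4 and 5% of PV4 at 150 pA
from 700 ms; feedback states drive the same fractions in layer 5, 2/3,
2/3+5, 6 or 2/3+5+6; the combined state applies the feedforward drive at
500 ms and the layer-5 feedback drive at 1100 ms. Perturbations add a
30 pA DC epoch (negative amplitudes allowed) to *all* neurons of one of
the 16 complete-layer groups — the whole group rather than the 25%/5%
state-drive subsets, which is the plain reading of injecting current "into
each group"; the fraction is exposed as a parameter for the alternative.

The DC idealisation of afferent drive rests on the diffusion
approximation: many small synaptic inputs sum to an approximately constant
mean current, so no extra noise term is attached to protocol currents.

# Numerical scheme

All dynamics advance on a fixed grid, $dt = 0.1$ ms by default:

* **Membrane:** forward Euler; spikes detected at step end; reset and
  refractory clamp applied immediately.
* **Linear gating (AMPA, GABA, NMDA rise):** exact exponential decay
  (`s ← (s + increments)·e^{-dt/τ}`), so impulse responses match the
  closed forms at machine precision rather than the ~2.5% error forward
  Euler would make at $\tau = 2$ ms.
* **NMDA channel fraction:** forward Euler (the $(1-s)$ term is
  nonlinear); a step that would leave $[0,1]$ aborts the run with a
  diagnostic rather than clamping silently.
* **Spike transmission:** a fixed 0.1 ms latency — one step at the default
  resolution, held fixed (as a ring buffer of $\lceil 0.1/dt \rceil$
  steps) when $dt$ is refined so that refining the integrator does not
  change the physical model. No longer axonal delays are modelled.
* **Background events** are binned per step (the Poisson count for each
  neuron and step is drawn and applied as that many unit deltas); event
  times within a step are not resolved.
* **Initial conditions:** all neurons start at $V_{rest}$ with zero
  gating; deterministic and state-free.
* **Divergence guard:** $|V| > 500$ mV aborts with the neuron and step
  named.

One documented sensitivity: in a fluctuation-driven regime the discrete
threshold check acts as a sampled first-passage detector, so halving $dt$
to 0.05 ms raises population rates by roughly 10% on the synthetic column.
This is a generic property of fixed-grid LIF integration, not of this
implementation; all quantitative analyses in the package therefore fix
$dt = 0.1$ ms, and the integration-robustness test asserts agreement
within 15% rather than a tighter bound the scheme cannot honour.

## Seed discipline

A single master seed spawns named substreams (connectivity, background,
per-epoch target selection), so a run is a pure function of
(network files, protocol, seed, dt). Appending a perturbation epoch leaves
every other stream untouched: a perturbation of amplitude 0 reproduces the
unperturbed run spike for spike.

# Perturbation analysis

A sweep establishes a state, lets it settle (1 s by default after the
drive onset), and then runs one simulation per perturbable group with a
perturbation epoch covering a 3 s measurement window, plus one state-only
simulation. The response matrix entry $R_{XY}$ is the percent change of
population X's mean rate under perturbation of Y, measured against the
state-only run over the *same* window. Because all runs share the master
seed, the state-only run is the exact counterfactual: an amplitude-0 sweep
gives an exactly zero matrix, and any nonzero entry is attributable to the
perturbation alone. (Measuring the baseline in the pre-perturbation window
of the same run — the other natural reading — agrees up to window noise
but breaks the exact-zero property.)

Zero-baseline entries make the percent change undefined; they are flagged
and excluded — treated as category 0 and masked from Frobenius distances —
never silently set to 0 or ±∞, and they are excluded from marked-change
counts. The diagonal (a group observing itself) is excluded from counts.

Derived views, all computable from one stored sweep: threshold
categorisation (+1/−1 for changes strictly beyond ±20%; boundary equality
is category 0), the categorical comparison between two states (white on
agreement, red for transitions toward increase, green toward decrease),
entrywise percentage-point differences with sign-flip flags, marked-change
counts with their positive fraction, and pairwise Frobenius distances.

Spike-train statistics follow standard definitions: group mean rates over
stated windows; sliding-window (100 ms, centred) rate traces — the centred
convention makes a step input visible half a window early; CV of ISI per
neuron (neurons with fewer than 3 spikes excluded); the Golomb–Rinzel
voltage synchrony $\chi$ (the ratio of the variance of the mean trace to
the mean single-trace variance, square-rooted) — adopted as the standard
voltage-based reading of "synchrony measured from membrane potentials";
and a Welch power spectrum (1 s Hann segments, 50% overlap — defaults
chosen since no spectral parameters are prescribed anywhere).

# The synthetic column

The experimentally constrained probability/strength/width matrices are an
optional user-supplied input (`read_bundle()` documents the CSV layout);
nothing is downloaded. For self-contained use and testing,
`synthetic_bundle()` generates a column whose *structure* matches the real
one — 17 groups, 85/15 laminar composition, probabilities in [0, 0.3]
with stronger within-layer than across-layer coupling, strengths in
[0.1, 2] mV, widths in [50, 300] µm — and whose wiring carries the
canonical microcircuit motifs a cortical modeller would expect:

* within-layer E→I and I→E loops, PV-dominated;
* a feedforward excitatory chain out of layer 4 (E4→E2/3→E5/E6, plus
  direct E4→E5/E6);
* layer-5 pyramids recruiting PV/SST cells across layers while projecting
  only weakly to other layers' pyramids (the top-down motif);
* layer-6 projections onto PV cells of other layers (translaminar gain
  control);
* VIP→SST disinhibition, including from layer 1.

Background rates (E 1950, PV 2000, SST 1000, VIP 1100 events/s) were
chosen once so that the 5000-neuron column sits in a low-rate,
inhibition-dominated asynchronous regime — pyramidal rates of a few Hz,
interneurons faster, every group active within 3 s. With these defaults
the column reproduces the qualitative state signatures: feedforward drive
raises pyramidal rates in all layers; layer-5 feedback raises E5 and
lowers pyramidal rates elsewhere; removing inhibitory output raises every
group's rate; stronger feedforward drive leaves fewer marked perturbation
changes.

What the synthetic column does *not* emulate: the actual measured
probability/strength values (its matrices are seeded draws plus motifs,
not data), per-group parameter heterogeneity beyond cell type, tuned
in-vivo-matched rates, or distance-dependent per-pair connectivity. Tests
passing on it therefore validate the machinery and the qualitative circuit
logic, not quantitative agreement with recordings; quantitative targets
require the real matrices.

# Problem sizes and costs

The package's own test suite exercises full columns at 800–2000 neurons
with 0.4–0.8 s measurement windows — sizes at which a 16-population sweep
(17 simulations) completes in tens of seconds while every statistic keeps
its meaning. The shipped defaults (5000 neurons, 3 s windows) match the
published design; a full default sweep is minutes of compute on one core.

# Worked example

```{r example}
library(colspike)

bundle <- synthetic_bundle(seed = 1)
column <- build_column(bundle, N_total = 5000, seed = 1)

plan <- experiment_plan(state = "ff", master_seed = 1)
sweep <- perturbation_sweep(plan, column)
print(sweep)

cat_m <- categorize(sweep)
count_marked(cat_m)
```

# Known limitations

Point neurons only (no dendrites or multi-compartment effects), no
synaptic delays beyond the fixed transmission latency, no short-term
plasticity, no conductance-based (spike-train) afferents for the
feedforward/feedback pathways, no explicit thalamus, and no
distance-dependent per-pair connectivity. These follow the model the
package implements rather than being implementation shortcuts.
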