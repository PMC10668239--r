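---
title: "Modelling gamma oscillations and NMDA-receptor block in a cortical spiking network"
author: "gammanet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling gamma oscillations and NMDA-receptor block in a cortical spiking network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(gammanet)
```

## The scientific question

Dissociative NMDA-receptor (NMDAR) antagonists such as ketamine
paradoxically *increase* cortical excitability and gamma-band (30-90 Hz)
power, and produce psychotomimetic symptoms. A candidate mechanism is
disinhibition: if antagonists bind NMDARs on fast-spiking (FS)
inhibitory interneurons with higher affinity than on regular-spiking
(RS) pyramidal cells, partial block removes more excitatory drive from
the inhibitory population than from the excitatory one, and the network
is released from inhibition.

`gammanet` implements a complete, tested simulation-and-analysis
pipeline for studying this mechanism in a sparsely connected cortical
network model: adaptive exponential integrate-and-fire (AdEx) neurons of
two classes, conductance-based AMPA, GABA-A and voltage-dependent NMDA
synapses, Poissonian external drive, a kernel-based local field
potential (LFP) proxy, Welch spectral analysis with gamma/asynchronous
classification, synaptic charge ratios, and a paired-simulation
responsiveness protocol.

## The model

### Neurons

Each neuron follows the AdEx equations

$$C \frac{dV}{dt} = -g_L (V - E_L) + g_L \Delta\, e^{(V - V_{th})/\Delta}
  - w - I_{syn}, \qquad
  \tau_w \frac{dw}{dt} = a (V - E_L) - w,$$

with a spike recorded when \(V\) reaches the cut potential (equal to
\(V_{th}\) by default), a reset to \(V_{rest}\), a 5 ms refractory clamp
at \(V_{rest}\), and a spike-triggered adaptation increment \(w \to w +
b\). During the clamp \(w\) keeps evolving with \(V = V_{rest}\); since
\(V_{rest} = E_L\) for both presets, this is a pure decay. The membrane
is clipped at the cut potential inside the exponential to prevent
overflow of the forward-Euler step.

Two presets are provided ([rs_params()], [fs_params()]): both share
\(C = 150\) pF, \(g_L = 10\) nS, \(E_L = V_{rest} = -65\) mV,
\(\tau_w = 500\) ms and \(T_{ref} = 5\) ms. RS cells have
\(\Delta = 2\) mV, \(a = 4\) nS, \(b = 20\) pA and \(V_{th} = -50\) mV;
FS cells have \(\Delta = 0.5\) mV, \(a = b = 0\) and
\(V_{th} = -47.5\) mV.

The RS threshold deserves a note, because it is the single most
consequential number in the model. With the leak at \(-65\) mV, a
threshold of \(-50\) mV places the excitatory population in the
fluctuation-driven regime under the default drive (the drive-only
operating point is near \(-55\) mV): sparse, self-sustained, irregular
firing exists and the pyramidal-interneuron gamma (PING) loop can
operate. Pushing the threshold far above the operating point (e.g.
\(-40\) mV) creates a >200 pA current barrier that stochastic drive
cannot cross: the network then admits only total silence or, once
forced across, a refractory-locked runaway in which every neuron fires
at \(1/T_{ref}\). We verified both failure modes by direct simulation,
including attempts to bootstrap the high-threshold network through its
own NMDA current: the magnesium block suppresses NMDA conductance
exactly at hyperpolarized voltages, so the gating charge built up by an
ignition volley decays (with \(\tau_{decay} = 200\) ms) faster than the
voltage can climb, and the bootstrap always loses the race.

### Synapses

Each postsynaptic neuron carries one AMPA and one GABA-A conductance
that jump by a quantal amount \(Q\) on each delayed presynaptic spike
and decay exponentially (\(\tau_{AMPA} = 1.5\) ms,
\(\tau_{GABA_A} = 7.5\) ms). NMDA channels use the saturating
biexponential gating scheme: each presynaptic *source* \(j\) (an RS
neuron, or a stimulus train) carries a gating pair

$$\frac{ds_j}{dt} = -\frac{s_j}{\tau_{decay}} + \alpha x_j (1 - s_j),
  \qquad
  \frac{dx_j}{dt} = -\frac{x_j}{\tau_{rise}} + \sum_k \delta(t - t_k),$$

with \(\tau_{rise} = 2\) ms, \(\tau_{decay} = 200\) ms,
\(\alpha = 0.5/\mathrm{ms}\), and the postsynaptic NMDA current is

$$I_{NMDA} = Q_{NMDA} \Big(\sum_{j \in \mathrm{pre}(i)} s_j\Big)
  (V - E_{NMDA})\, B(V), \qquad
  B(V) = \frac{1}{1 + e^{-0.062 V}\,[\mathrm{Mg}^{2+}]_o / 3.57}.$$

Because \(s_j\) depends only on the spike train of source \(j\), one
gating pair per source suffices — the implementation is exactly the
per-synapse saturating model at \(O(N_{pre})\) state. This summation is
essential: a single per-neuron gate bounded by 1 would cap the entire
NMDA conductance at \(Q_{NMDA} \le 1\) nS (a few pA of current), making
the NMDA weights dynamically inert and the antagonist manipulation
meaningless. With summation, NMDA carries a substantial slow excitatory
current whose strength is set by \(Q_{NMDA}\) — the handle the
antagonist manipulation turns.

Reference quantal strengths are \(Q_{AMPA} = 2.3\) nS and
\(Q_{GABA_A} = 4.75\) nS. At the default in-degrees (~400 recurrent
excitatory, ~100 inhibitory, ~500 external contacts per neuron) these
place the network in an inhibition-dominated balanced regime. The
choice is deliberately conservative: with per-spike excitatory
potentials much above ~1.5 mV the excitatory cascade outruns the
delayed inhibition and a stable paroxysmal attractor (all neurons at
\(1/T_{ref} \approx 196\) Hz) becomes reachable from the working state.
All reversal potentials, time constants, the magnesium concentration
(1 mM) and the uniform 1.5 ms delay are fixed package-wide; every value
is a config key.

The healthy reference condition is \(Q_{NMDA}^{RS} = 0.8\) nS,
\(Q_{NMDA}^{FS} = 1.0\) nS. NMDAR antagonists are modelled purely as a
movement of this pair along a trajectory to \((0.213, 0.2)\) nS —
the FS weight falling faster, encoding the higher antagonist affinity
for receptors on interneurons ([nmda_trajectory()]).

### Network and drive

4000 RS and 1000 FS neurons; every ordered pair of distinct neurons is
connected independently with probability 0.1 (one Bernoulli draw per
pair, so in-degrees are Binomial); RS spikes drive AMPA+NMDA, FS spikes
GABA-A. The external drive is a pool of 5000 independent Poisson trains
wired to the neurons with probability 0.1, feeding AMPA only
(\(Q_{ext} = 0.8\) nS); a second, separate 5000-train pool delivers the
Gaussian-envelope stimulus (SD 50 ms) and feeds both AMPA and NMDA.
Because the two pools are wired with 10% probability, any two neurons
share ~10% of their drive — a deliberate common-input correlation that
the model inherits.

A background rate of 3 Hz per train yields gamma-band collective
oscillations; 2 Hz yields a sparser regime used as the
asynchronous-state comparison (see Limitations).

All spike trains are sampled in R by [sample_poisson_trains()] as
per-step Bernoulli events on the simulation grid (exact thinning for
inhomogeneous rates), and handed to the compiled engine as event lists.
The engine itself contains no random number generator: a run is a pure
function of the graph, the configuration and the drive/stimulus
realizations, which makes common-random-number pairing in
[paired_run()] exact by construction.

### Integration

Forward Euler at `dt = 0.1` ms. The per-step order is fixed and
documented (it matters for Euler): deliver delayed arrivals; advance
gating/conductances; evaluate currents at the pre-step voltage; Euler
step \(V, w\); detect/reset/refractory; schedule the new spikes after
the delay. Delays are handled by per-channel ring buffers of
`delay/dt` slots, so delivery is exact to the step. The per-neuron NMDA
gating sums may be refreshed on a coarser grid (0.5 ms in the scale
profiles; the gating itself advances every step) — the gating evolves
on 2-200 ms timescales, and the refresh interval is an order of
magnitude below the fastest of them.

### Ignition

The active regime is self-sustained and lies well above the drive-only
resting state, so a simulation started at rest can remain silent. The
experiment drivers therefore start each run with membrane potentials
drawn uniformly between \(E_L\) and threshold and with a drive ramp
(`mu + max(0, 3.5 - mu) * exp(-t / 150 ms)`) that decays inside the
discarded transient (500 ms by default). The ramp is part of the seeded
background realization and hence identical across paired runs.

## Analysis pipeline

**LFP proxy.** 50 neurons (40 RS / 10 FS) are placed uniformly at
random in a 400 um square with the electrode at its centre; the LFP is
the sum over their spikes of a unitary-LFP kernel: Gaussian in time
(SD 2.1 ms), amplitude decaying with distance (space constant 200 um),
peak delayed by 10.4 ms plus conduction at 200 um/ms; inhibitory
kernels are larger than excitatory ones and of opposite sign. The
kernel constants only scale and smooth the trace — every spectral
statistic in the package is amplitude-invariant (normalized PSDs,
peak-to-baseline ratios), so none of the conclusions depend on them.

**Spectra.** [welch_psd()] implements Welch's method with a periodic
Hamming window of 0.25 s and 125-sample overlap at the 1 kHz LFP rate
(4 Hz resolution), mean-detrended segments, one-sided density scaling;
it is cross-checked in the test suite against an independent reference
implementation to 1e-10. A state is labelled *gamma* when the 30-90 Hz
peak exceeds 5x the median 20-200 Hz power (excluding the peak's
+/- 8 Hz neighbourhood), else *AI*; the factor 5 is a documented
package choice, exposed as `threshold`.

**Charges.** For recorded neurons, AMPA and NMDA current snippets are
averaged aligned on the delayed excitatory arrival times and integrated
(trapezoid) over exactly 10 ms from the input; the NMDA/AMPA ratio uses
absolute charges.

**Responsiveness.** From a stimulus/no-stimulus pair sharing the
background realization, \(R = (N^S - N) / (T\,N_n)\) in
spikes/s/neuron, counted in a `T` = 500 ms window centred on the
stimulus (capturing +/- 5 SD of the 50 ms envelope); when a population
is selected, \(N_n\) is that population's size.

**Experiments.** [sweep_qnmda()] maps the NMDA weight plane;
[trajectory_experiment()] runs the antagonist trajectory and collects
rates, normalized PSD summaries, state labels and mean potentials;
[responsiveness_protocol()] and [fast_nmda_variant()] (NMDA decay 50 ms)
run the stimulus-response curves. Multi-repeat trend claims use
one-sided sign tests across repeats at alpha = 0.05.

## Scale profiles

`sim_profile("paper")` is the full study: 5 s runs, 10/50/15 repeats
for sweep/trajectory/responsiveness. `sim_profile("desk")` keeps the
full 5000-neuron network but uses 2 s runs (1.5 s for responsiveness)
and 2-5 repeats, sized for a single CPU; the test suite runs entirely
on this profile. We deliberately do *not* shrink the network and
rescale quanta: a 1/5-size network with 5x quanta preserves mean
conductances but multiplies per-event potentials five-fold (~14 mV
EPSPs), which pushes the model into a clock-like, fully synchronized
gamma whose responses to the NMDA manipulation differ qualitatively
from the full-size network. Duration and repeat count are the only
honest scale knobs here.

## What the defaults reproduce, and known limitations

With the reference parameters the package reproduces, robustly across
seeds at desk scale:

- a sparse, self-sustained network state at 3 Hz drive with a dominant
  30-90 Hz LFP peak (RS ~4-5 Hz, FS ~13-15 Hz);
- along the antagonist trajectory: a monotone *increase* of the RS
  firing rate (disinhibition-driven excitability increase), an
  *increase* of the gamma peak power, and a hyperpolarization of the FS
  mean potential;
- an NMDA/AMPA charge structure in which the NMDA current is a major
  slow excitatory component for both classes;
- exactly zero responsiveness at zero stimulus amplitude (a property of
  the common-random-number design, not a statistical statement), and a
  higher RS responsiveness under block in most repeats.

Known limitations, found and characterized while building the package:

- **Two blocked-state regimes.** At strong block the network lands in
  either a *disinhibited* regime (RS rate up, gamma power up, FS mean
  potential down; FS rate roughly flat and RS mean potential slightly
  down, both dragged by the stronger synchrony and adaptation) or a
  *collapse* regime (FS rate collapses, RS depolarizes, but RS rates
  fall). Which one a given seed reaches depends on the stochastic
  drive; the reference parameters favour the disinhibited regime. The
  conjunction "RS rate up AND RS potential up AND FS rate down AND FS
  potential down" in a single run sits on the boundary between the two
  regimes and is not robust in this model.
- **The 2 Hz state is not spectrally asynchronous.** Lowering the drive
  to 2 Hz reduces rates and gamma power but the LFP still shows a
  dominant gamma-band peak, so [classify_state()] labels it gamma at
  the default threshold. Consequently the gamma-masking effect — higher
  responsiveness in the asynchronous state — is absent here: the 2 Hz
  state responds somewhat *less* than the 3 Hz state.
- **Metastability under strong block.** At the trajectory endpoint the
  active state can drop into a much sparser state during long runs;
  desk-profile trajectory runs are kept at 2 s partly for this reason.
- **Gamma frequency.** The dominant peak sits at 32-48 Hz (low gamma)
  and moves non-monotonically along the trajectory (up at intermediate
  block, down at strong block); a monotone downward shift of the peak
  frequency is not reproduced.
- The synthetic drive emulates stationary, identically distributed
  Poisson inputs with shared-pool correlations; real cortical input is
  neither stationary nor Poisson, so passing trend tests here says
  nothing about temporal structure beyond these assumptions.

## Numerical choices, collected

| Choice | Value | Why |
|---|---|---|
| Integration | Euler, dt = 0.1 ms | matches the synapse jump semantics; update order fixed and documented |
| Spike cut | V_th (config `v_cut`) | detection at the effective threshold; exponential term bounded by g_L*Delta at detection |
| Exponential guard | V clipped at v_cut | Euler can overshoot arbitrarily on the spike upswing |
| NMDA gating clip | s in [0, 1] after each step | forward Euler can overshoot the saturating ODE at large x |
| Delays | ring buffers, multiples of dt | exact delivery, O(1) per event |
| Transient | 500 ms discarded | settling of the ignition ramp and gating sums |
| NMDA sum refresh | 0.5 ms (profiles), dt (default) | gating timescales are 2-200 ms |
| V traces | 1 ms population means; full-dt per recorded id | analyses need means; charge analysis needs dt resolution |
| Classification | peak >= 5x median(20-200 Hz) | dominance criterion; factor 5 exposed as config |

The problem sizes used by the default test-suite runs are those of the
desk profile: full 5000-neuron graphs, 1.5-2 s simulations, 5 repeats
for trajectory and responsiveness experiments, one 2 s run for the
charge analysis, and miniature (10-250 neuron) fixtures for the engine
oracles.
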