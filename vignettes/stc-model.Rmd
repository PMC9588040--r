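---
title: "Model and methods: neuromodulator-dependent synaptic tagging and capture in a spiking network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(stcnet)
```

## The scientific question

A memory trace is laid down within seconds, but whether it survives
the following hours is decided later, by synaptic consolidation.
Neuromodulators such as dopamine and norepinephrine, released when an
event turns out to matter, lower the threshold for the synthesis of
plasticity-related proteins and thereby gate which synapses transfer
their changes into a stable late phase.  `stcnet` implements a
recurrent spiking network in which this gating can be studied
quantitatively: how does the *concentration* of a neuromodulator in the
minutes-to-hours after learning select the synapse populations that
consolidate, and with them the neural code (firing-rate pattern vs
precise spike times) that the network can still express at recall
eight hours later?

## The model

**Neurons.** `N_e` excitatory and `N_i` inhibitory leaky
integrate-and-fire neurons (default 1600 + 400).  The membrane
potential of neuron $i$ follows

$$\tau_m \dot V_i = V^{rev} - V_i + V^{PSP}_i + V^{bg}_i + V^{stim}_i,$$

with a spike whenever $V_i \ge V_{th}$, reset to $V^{reset}$ and a
2 ms refractory clamp.  $V^{PSP}_i$ is the sum of delayed exponential
postsynaptic potentials from within the network (axonal delay 3 ms,
synaptic time constant 5 ms); inhibitory weights enter it with a
negative sign, the convention adopted here because the weight table
lists magnitudes only and inhibition must hyperpolarise.  $V^{bg}$ is
an Ornstein-Uhlenbeck process with mean $R_m I^0 = 1.5$ mV and
stationary standard deviation $R_m\sigma_{wn}/\sqrt{2\tau_{syn}} = 5$
mV, standing in for diffuse input from outside the network.  $V^{stim}$
is a second, independent OU process representing `N_stim = 4` putative
input fibres firing at the stimulation frequency; it is computed
independently per stimulated neuron.  Its stationary mean
$N_{stim} f_{stim}\cdot 1\,\mathrm{s}\cdot h_0$ is large (1.68 V at
100 Hz), so stimulated neurons fire near the refractory limit during
pulses; network activity elsewhere is kept in check by the
recurrent excitatory/inhibitory balance.

**Synapses.** Connections are drawn independently with probability
`p_c = 0.1` for every ordered pair (no self-connections; at most one
synapse per ordered pair).  Weights involving inhibitory neurons are
fixed ($2h_0$, $4h_0$, $4h_0$ for E→I, I→E, I→I).  Every E→E synapse
carries two dynamic components, a fast early-phase weight $h$ and a
slow late-phase weight $z$, with total weight $w = h + h_0 z$:

* **Calcium** at the postsynaptic site decays with $\tau_c = 48.8$ ms
  and jumps by $c_{pre} = 0.6$ per presynaptic spike (delayed by
  18.8 ms) and $c_{post} = 0.1655$ per postsynaptic spike.
* **Early phase**: $h$ relaxes toward $h_0$ (rate $0.1/\tau_h$),
  potentiates toward 10 mV while calcium exceeds $\theta_p = 3$,
  depresses while calcium exceeds $\theta_d = 1.2$, with an additive
  noise term active only above those thresholds.  We clip $h$ to
  $[0, 10]$ mV — the lower bound prevents noise-driven negative
  weights, the upper bound is the potentiation attractor.
* **Tag**: the synapse is tagged while $|h - h_0| > \theta_{tag}$.
* **Proteins**: each neuron synthesises plasticity-related proteins
  ($\tau_p$ = 1 h, saturating at $\alpha = 1$) while the summed
  early-phase change of its incoming synapses, $\sum_j |h_{ji} - h_0|$,
  exceeds the neuromodulator-dependent threshold
  $\theta_{pro}(NM) = 1/(NM + 0.001)$ mV.  The sum is recomputed from
  the current weights, not accumulated.
* **Late phase**: while a synapse is tagged *and* proteins are present,
  $z$ integrates toward 1 (LTP tag) or $-0.5$ (LTD tag) with
  $\tau_z$ = 1 h; those drift targets are also the clipping bounds.

All defaults are available from `model_params()` and documented there
with units.

## Protocol

Activity settles for 10 s; the learning stimulus (three 0.1 s pulses
separated by 0.4 s breaks, default 60 Hz) targets the 150-neuron core
assembly; a single 0.1 s recall pulse at 100 Hz targets the first half
of the assembly either 10 s or 8 h after the learning onset (recall
onset 20.0 s / 28810.0 s, rate-evaluation times 20.1 s / 28810.1 s).
The printed evaluation times fix the recall onset at learning onset
plus 10 s / 8 h; we follow those times where a phrase-level reading
("after the end of the learning stimulus") would disagree by 1.1 s.

For the 8 h condition the spiking dynamics are computed until 11.6 s
(0.5 s after the last pulse, by which time the stimulus transients have
decayed), the consolidation gap is *fast-forwarded*, and spiking
resumes 0.5 s before the recall pulse so membrane and drive traces
re-equilibrate.  The fast-forward exploits that without stimulation
calcium stays below the plasticity thresholds: early-phase deviations
then decay exponentially (computed analytically), while tags, protein
pools and the late phase are integrated on a 0.1 s grid.  The
stochastic early-phase term is inactive below the calcium thresholds
and therefore absent during the gap.  A dedicated test verifies that
the fast-forward matches brute-force spiking integration over a
two-minute quiet gap, and fine-step (0.2 ms) integration of the gap
dynamics over ten minutes, to the documented tolerances.

## Numerical choices

* Forward Euler-Maruyama at `dt` = 0.2 ms for membrane and OU
  equations; white-noise terms have per-step variance $1/dt$.
* The PSP sum is carried as one per-neuron exponential trace with exact
  per-step decay $e^{-dt/\tau_{syn}}$, which makes it *identical* to
  the explicit double sum over spike times (tested to $10^{-9}$ mV).
* Calcium decays with the exact factor $e^{-dt/\tau_c}$; pre/post
  contributions are applied as jumps.
* Synapses are updated event-lazily: a synapse is stepped every `dt`
  only while its calcium exceeds $\theta_d$ (the only regime in which
  the fast early-phase terms and the noise are active); below
  threshold, calcium decay and the slow relaxation of $h$ toward $h_0$
  are applied analytically when the next event arrives, and the whole
  displaced population is re-synchronised every 0.1 s, when the late
  phase is also advanced.  This keeps full-size simulations tractable
  without changing the integrated equations beyond $O(dt)$
  bookkeeping.
* The threshold test uses $V \ge V_{th}$ after the Euler update; spike
  times are grid times, no crossing interpolation.
* All randomness, in R and in the C++ core, is drawn from R's RNG, so
  a single seed makes topology, simulation and analysis bit-for-bit
  reproducible.

## Analysis suite

* `sliding_rate()`: spike count in the trailing half-open window
  $(t - 0.5\,\mathrm{s}, t]$ divided by the window; the trailing
  convention makes the 20.1 s evaluation cover the whole recall pulse.
* `pattern_completion_q()`: $Q = (\bar\nu_{ans} - \bar\nu_{ctrl}) /
  \bar\nu_{as}$ over the recall-stimulated assembly half, the
  non-stimulated half, and the control population.
* `rate_mutual_information()`: plug-in mutual information between the
  per-neuron rate values at learning (11.0 s) and recall, in bits.
  Rates from a 0.5 s window are inherently discrete (multiples of
  2 Hz), so the empirical joint histogram over exact values is used
  with no extra binning parameter.
* `pca_dimensionality()`: number of principal components retaining 70%
  of the variance of the (neurons × time-bins) recall raster, neurons
  treated as samples; the orientation is exposed as an option because
  it is not innocuous.
* `spike_time_stability()`: fraction of a neuron's 1 ms spike bins in
  the final learning pulse that recur in the recall pulse; zero-spike
  neurons carry no score and are excluded from averages.
  `shuffle_raster()` provides the per-neuron bin-permutation control.
* `fit_ridge_readout()`: ridge regression of a Gaussian random-walk
  target on the concatenated binned rasters of the three learning
  pulses and the recall pulse, evaluated on the recall segment.  The
  intercept column is penalised together with the other weights, as
  the objective $\lVert y - Xw\rVert_2^2 + \alpha\lVert w\rVert_2^2$
  states; this deviates from common library defaults and is deliberate.
  Subsamples of size `round(p_out * pool)` are drawn without
  replacement.

## Scaled-down study conditions

Full-size sweeps (1600 + 400 neurons, 50 networks per condition) are
supported but long-running.  The package therefore ships a
quarter-size preset, `scaled_params()` (400 + 100 neurons, assembly
40, recall set 20), used by the test suite with 10 networks per
condition and a learning frequency of 60 Hz.

The protein-synthesis sums $\sum_j|h_{ji} - h_0|$ scale with the
number of potentiated incoming synapses, so the neuromodulator
concentrations that realise the none/low/moderate/high consolidation
regimes shift with network size.  `calibrate_nm_levels()` fixes them
from the model's own statistics: it runs the learning phase once,
measures the post-learning sums in core and non-core neurons, and
places $\theta_{pro}$ for *low* at the geometric mean of the core 10%
quantile and the non-core median (protein synthesis mostly confined to
the core), for *moderate* at the non-core median, and for *high* at
the non-core 10% quantile (synthesis nearly everywhere).  *None* is
always $NM = 0$, whose threshold of 1000 mV exceeds any attainable
sum.  Selectivity of consolidation then rests on the tags: only
core-internal and outgoing synapses are driven past the tagging
threshold by learning, so the neuromodulator level decides whether the
core alone (low) or core plus outgrowth (high) is stabilised, while
incoming and control synapses stay untagged and unconsolidated.

At the quarter scale the calibrated levels lie near 0.05–0.10 rather
than the reference 0.06–0.18, and the sums they are compared against
are about four times smaller than at full size.  The test thresholds
on the scaled study (e.g. "mean late-phase weight of outgoing synapses
under low neuromodulation is less than half that of core-internal
synapses") encode the qualitative claims with margins; they are not
estimates of full-size effect sizes.

## What the fixture generator does and does not emulate

`generate_fixture()` produces paired learning/recall binned rasters
with controllable firing rate, bin-wise overlap and latent rank, plus
labelled weight tables.  It reproduces the *statistical* structure the
analysis functions consume — per-neuron counts, exact-bin recurrences,
low-rank temporal structure — but none of the network's dynamical
features: no refractoriness beyond one-spike-per-bin, no E/I balance,
no correlation between rate and stability, no relation between weights
and activity.  Tests passing on fixtures therefore validate the
measures, not the biology; the scaled-down simulated study is what
probes the model's behaviour.

## Known limitations

* Current-based, not conductance-based synapses; no synaptic rise
  time.
* One abstract neuromodulator scalar; receptor kinetics, multiple
  modulator species and excitability effects are out of scope.
* A single cell assembly; no replay during consolidation and no
  systems-level consolidation.
* The fast-forward assumes spontaneous spiking during the gap is too
  sparse to move calcium above threshold; with parameter sets that
  produce high background rates, the 8 h protocol should be run with
  spiking throughout (at full cost) instead.
* The stimulus OU drive follows the printed mean
  $N_{stim} f_{stim} \cdot 1\,\mathrm{s}\cdot h_0$, which saturates
  stimulated neurons during pulses for any commonly used frequency;
  consequences for the frequency axis of sweeps (compression of the
  dynamic range toward low frequencies) are inherited from that
  definition.

## Problem sizes used by the shipped tests

Unit tests run on networks of 2–75 neurons and on the quarter-size
preset for single runs; the phenomenology study uses the quarter-size
preset with 10 network realisations × 4 neuromodulator levels × 2
recall times.  A single quarter-size run (20 s of spiking plus the 8 h
fast-forward) takes a few seconds on one core; a full-size run takes
on the order of a minute, and the 50-network reference grids are meant
for batch execution via `stcnet sweep`.
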