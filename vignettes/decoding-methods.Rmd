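---
title: "Decoding continuous motor signals with a spiking neural network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding continuous motor signals with a spiking neural network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snndecoder)
```

## The model

`snndecoder` learns to predict continuous target signals (rectified
muscle-activity envelopes, kinematic trajectories) from multichannel
brain-signal time series (EEG-like, uniformly sampled). The pipeline has
three stages, all operating on spikes:

1. **Threshold codec.** Each channel is differenced sample to sample and a
   spike is emitted whenever the absolute difference reaches the channel
   threshold `th = mean(|d|) + c * sd(|d|)`, with the sign of the
   difference as the spike polarity. Decoding inverts this: starting from
   the stored initial value, the reconstruction steps by `±th` at every
   spike. Polarity is kept internally but the supervised layer consumes the
   unsigned view, because a spike-pattern association neuron cannot be
   trained on mixed-polarity trains.

2. **3D spiking reservoir.** Leaky integrate-and-fire (LIF) neurons are
   laid out on a grid inside an ellipsoidal head volume and labelled with a
   coarse region code (octant × depth band — a deliberate simplification of
   a stereotaxic atlas; a user-supplied labelled coordinate table can be
   used instead). Input channels are mapped to their nearest neurons, which
   act as relays: one encoder spike, one reservoir spike. Synapses are
   initialised by the small-world principle (connection probability
   decaying exponentially with distance inside a cut-off radius) and evolve
   under a fire-triggered variant of spike-timing-dependent plasticity
   (STDP): weights change only when a neuron fires — never on mere spike
   receipt — and a fire event updates both the firing neuron's incoming
   synapses (potentiation when the presynaptic partner fired earlier) and
   its outgoing synapses (depression when the postsynaptic partner has not
   fired since), using the exponential window
   `W(x) = A+ exp(-x/tau+)` for `x > 0`, `-A- exp(x/tau-)` for `x < 0`,
   and `W(0) = 0`. The all-pairs double-sum form of the update is exposed
   separately (`stdp_total_update()`) for offline analysis; the online rule
   uses nearest spikes only, since per-event increments of the
   fire-triggered variant are not uniquely determined by the window alone.

3. **Evolving SPAN output layer.** For every target channel (and for the
   movement-onset event) a *population vector* of spike pattern association
   neurons (SPANs) is grown incrementally. Each member receives the
   alpha-convolved spike trains of one anatomical cluster,
   `I(t) = sum_i w_i sum_f alpha(t - t_i^f)` with
   `alpha(t) = e t / tau_s * exp(-t / tau_s)` (unit peak at `t = tau_s`),
   fires where the current reaches `th_m`, and is trained with the
   spike-domain delta rule: for afferent `i`,
   `dw_i = lambda (e / tau^2) [ sum over (input, desired) pairs of
   (|dt| + tau) e^(-|dt|/tau) - the same sum over (input, emitted) pairs ]`.
   When no existing trained member reproduces a trial's desired train, a
   new member is spawned, wired to the next cluster in round-robin order,
   and trained on that trial. After the growth pass, members are validated
   on the training trials and weighted into a binary readout neuron whose
   state is 1 wherever the weighted mean of the members' alpha-convolved
   output trains reaches the readout threshold. Readout spikes are decoded
   back to continuous signals with the target-channel thresholds.

## Parameters that matter

All tunables live in `snn_control()`; times are in milliseconds, distances
in template units (mm).

| group | parameter | default | why |
|---|---|---|---|
| codec | `codec_factor` | 3 | input threshold factor; keeps input trains sparse and event-locked at realistic noise (the bare codec primitive defaults to 0.5) |
| codec | `codec_factor_targets` | 1 | finer spike resolution of the target waveform; also sets the decode step size |
| reservoir | `lif_threshold`, `tau_m`, `refractory_ticks` | 1, 20 ms, 5 | sub-critical, input-locked regime (below) |
| reservoir | `w_clip` | ±0.6 | caps single synapses below threshold so firing needs coincidence |
| stdp | `A_plus`, `A_minus`, `tau_plus`, `tau_minus` | 0.01, 0.01, 20, 20 | conventional exponential-window scales |
| span | `tau_s` | 100 ms | integration window of hidden SPANs; long enough to bridge an oscillatory burst, short enough to resolve the grasp and release responses as separate firing episodes |
| span | `lambda`, `step_cap` | 1, 0.05 | delta-rule scale and trust-region bound (below) |
| span | `th_m`, `max_epochs`, `match_tolerance` | 1, 100, 20 ms | firing threshold, training budget, spike-match tolerance (2 ticks at 100 Hz) |
| readout | `th_n`, `kappa` | 0.5, 0.8 | readout threshold in units of the median per-trial peak training current; retention factor of validation |
| evaluation | `max_lag_ms`, `smooth_ms`, `tau_s_pop` | 100, 50, 300 | correlation lag window; moving-average smoothing; alpha kernel used to turn member spikes into the continuous population trace compared against rectified targets (matched to the envelope timescale) |

## Numerical and design choices

**Reservoir operating regime.** A recurrent random graph of LIF neurons
with supra-threshold synapses is bistable: it either stays silent or, once
kicked, reverberates indefinitely — parameter scans across leak constants,
weight scales and inhibitory fractions found no robust intermediate regime,
because firing rectification makes inhibition ineffective at high rates.
The package therefore operates the reservoir *sub-critically*: every
synapse is capped at 0.6× the firing threshold, the membrane constant is
short (20 ms), and the refractory period long (5 ticks at 100 Hz), so a
neuron can only be recruited by near-coincident input and sustained
reverberation loops are broken. The cost is that with the default encoding
factor reservoir activity is dominated by the input relays plus sparse
coincidence recruitment near the electrodes; richer recurrent activity can
be explored by lowering `codec_factor`, at the price of background spikes.

**Delta-rule step control.** The raw delta-rule update grows linearly with
the number of (input × desired) spike pairs, so the same `lambda` that
works for single-spike tasks overshoots by orders of magnitude on dense
trains. `train_span()` keeps the update *direction* but rescales any epoch
step whose largest component exceeds `step_cap`. A zero update is never
rescaled, so the exact-match fixed point (`emitted == desired` implies
`dw == 0` term by term) is untouched.

**Fire-and-reset.** Taken literally, thresholded firing emits a spike at
every supra-threshold grid point. Members instead emit one spike per
upward threshold crossing and stay quiet until the current falls back
below threshold (hysteresis); the literal mode remains available
(`span_fire(..., hysteresis = FALSE)`) for oracle tests. The readout state
is kept literal (a binary comparator per tick), and its ticks double as
the decoded spike train.

**Readout normalisation.** The readout threshold is specified in
normalised-current units: the population current is divided by the median
of its per-trial peaks on the training data. The median (rather than the
maximum) makes the scale robust to a single outlier trial.

**Signed decoding of trajectories.** SPAN outputs are unsigned, but
kinematic reconstruction needs step directions. During fitting the signed
encoder spikes of each kinematic target are tallied per trial-relative
time slot; the smoothed tally's sign (+1 / −1, or none where training
trials never spiked) forms a per-slot profile. At prediction time, given
test trial starts, each readout spike takes the sign of its slot; spikes
in no-evidence slots produce no step. Rectified targets use all-positive
steps, and each trial is re-anchored at the channel's stored initial
value. Without trial-start information all targets fall back to
all-positive decoding — how a signed trajectory should be decoded from
unsigned spike trains in a fully cue-free stream is an open question of
this model class.

**Validation scoring.** A member's accuracy is the fraction of validation
trials whose emitted train matches the desired train exactly (equal
counts, every spike within the tolerance). On realistic dense targets this
is almost always zero for every member, which would silence the whole
population under the `kappa` rule; in that degenerate case a graded score
replaces accuracy: the cosine similarity between the desired and emitted
alpha-convolved trains, computed over the whole training session so that
firing outside trials is penalised too.

## The synthetic session generator

`generate_session()` emulates the event-locked structure of a cued
grasp-and-lift experiment: trials repeat at fixed intervals with a
jittered grasp onset and a release event one second later. Each input
channel carries band-limited oscillatory bursts (10–30 Hz carrier, 0.5 s
raised-cosine envelope) locked to *both* events — a trial whose only input
signature were the onset would make the targets' return phase undecodable
in principle — plus white noise at the configured amplitude SNR.
Muscle-like targets are amplitude-modulated rectified envelopes that rise
after the grasp and persist through the release movement; kinematic-like
targets are smooth rise–plateau–fall trajectories with slow, small sensor
noise. Ground-truth envelopes and event times are returned, and
`shuffled_control()` provides the negative control (targets circularly
shifted by at least one trial length).

What the generator does **not** emulate: volume conduction and channel
correlations, artefacts, non-stationarity, inter-trial variability of the
response topography, or any nonlinear EEG–EMG relationship. Passing the
synthetic benchmarks therefore demonstrates that the machinery recovers
event-locked structure under noise, not that it would reach the same
accuracy on real recordings.

Typical problem sizes used throughout the tests and scripts: 8 input
channels, 2 + 2 targets, 100 Hz, 20 training and 10 test trials (about 90
s of signal), a ~300-neuron reservoir, and 5 replicate seeds — small
enough to re-run interactively, large enough for the statistics to settle.

## A structural limit of single-afferent SPAN learning

One documented property deserves a caveat. With a *single* afferent the
delta rule controls only the scale of a fixed current trace, so the output
spike can only sit where the current first crosses threshold. Writing the
pair-proximity mass as `g(t)`, the learning flow has equilibria where
`g(t_out) = g(t_desired)`; besides the desired solution there is a
spurious *mirror* equilibrium near `2·mean(input) − t_desired`, and the
globally stable point is the later of the two. Numerically the stuck
outputs land exactly on the mirror prediction. Consequently, on the task
"one Poisson afferent at 10 Hz, one desired spike at 250 ms", convergence
to the desired time is structurally limited to roughly the fraction of
seeds whose input mass centre precedes the target (~50–60 %), even though
the task is *reachable* whenever any input spike precedes the target
window (~90 % of seeds). The corresponding acceptance check asserts the
90 % reachability figure and is expected to fail; it is kept as an honest
record of the rule's limitation rather than weakened. With many afferents
(the decoder's situation) the extra degrees of freedom remove the
constraint, which is why the end-to-end benchmarks pass.

## Known limitations

* The reservoir's sub-critical regime trades recurrent amplification for
  stability; STDP consequently reshapes mostly the synapses around input
  relays.
* Exact-match validation accuracy is uninformative on dense spike trains;
  the graded cosine score carries the weighting in practice.
* Latency figures from `latency_report()` are wall-clock measurements and
  hardware-dependent; they are reported, never asserted.
* The alpha-kernel stages delay every representation by roughly `tau_s`;
  predictions inherit a lag of one to three ticks, visible as non-zero
  best-correlation lags.
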