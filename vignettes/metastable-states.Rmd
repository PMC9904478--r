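---
title: "Metastable coding states in a taste-guided decision task: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metastable coding states in a taste-guided decision task: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`spikestates` implements two halves of one scientific program. The
*analysis half* extracts metastable states from ensembles of
simultaneously recorded spike trains collected while an animal performs
a four-taste, two-alternative choice (2-AC) task, classifies those
states by what they encode, and characterizes when in the trial each
kind of state appears. The *model half* is a clustered spiking network
of gustatory cortex that performs the same task, so that the same
analysis can be applied to simulated data, and so that simulated
optogenetic silencing can be related to behaviour.

This vignette explains the models, their assumptions, the tunable
parameters, the numerical choices, and the limits of what the shipped
tests demonstrate.

## The task and the data model

Four tastants map to two responses: sucrose (S) and quinine (Q) cue a
left lick, maltose (M) and octaacetate (O) a right lick. Because S and
M are sweet while Q and O are bitter, taste *quality* is deliberately
orthogonal to the rewarded *direction*. A session (`spike_session`)
holds per-trial spike times for 3–9 simultaneously recorded neurons,
plus two behavioural events per trial: the taste event and the decision
event. Their separation, the inter-event interval (IEI), averages
about 2.5 s.

Preprocessing (`preprocess_session`) clips spikes to the padded window
`[taste - 0.1 s, decision + 0.1 s]`, removes neurons whose mean rate
over the concatenated windows is below 2 Hz, and rejects sessions with
fewer than three surviving neurons. Bins everywhere in the package are
half-open `[t, t + dt)`.

## The spike-train hidden Markov model

Ensemble activity is reduced to one symbol per 2 ms bin: the index of
the neuron that fired, or a null symbol (`N + 1`) for silent bins; rare
multi-neuron bins are resolved uniformly at random under a recorded
seed. This discrete-symbol HMM approximates a Poisson-rate-vector HMM
at short bins, with the caveat that simultaneous firing is not
representable — which is also why the synthetic generator emits at most
one spike per neuron per bin.

Fitting (`fit_hmm`) is multi-start Baum–Welch: 10 random
initializations, at most 50 EM iterations each, stopping early only
when the changes in log-likelihood, transition and emission matrices
all fall below `1e-10`. Initial transition matrices are near-diagonal
(diagonal 0.99 with a small jitter that keeps runs distinct); initial
emission rows are normalized uniform(0,1) draws. The initial state
distribution is fixed uniform and is not a fitted parameter, so the
parameter count used by the BIC is `M(M-1) + MN`. The number of states
is chosen by minimizing `-2 LL + [M(M-1) + MN] ln B` over a candidate
range (`select_model`); `B` is the total number of bins.

Decoding computes forward–backward posteriors per bin (scaled, so
likelihoods stay finite for arbitrarily long sessions). A state is
*admissible* in an interval when its posterior stays at or above 0.8
for at least 50 consecutive ms; intervals never span trial boundaries.

Two numerical points worth knowing: EM converges to local optima, and
with uniform emission starts the best of 10 runs occasionally merges
two genuinely distinct states (the tests therefore demand recovery only
for well-separated rate vectors); and the reported log-likelihood is
recomputed once after the final M-step, so it corresponds exactly to
the returned parameters.

## Classification of decoded states

Per state, occurrence is "admissible at least once in the trial". The
pipeline uses correct trials only for the coding tests: (1) a 4-way
chi-squared test of equal occurrence proportions across stimuli at the
corrected level `1 - 0.95^(1/N_d)` (`N_d` = number of decoded states);
(2) if significant, the six pairwise Marascuilo comparisons — exactly
one stimulus with all three of its pairs significant makes a TasteID
state; (3) otherwise independent sweet-vs-bitter and left-vs-right
chi-squared tests yield Quality, Decision, Dual or Noncoding; (4)
Decision states are subclassified by their preferred direction in
correct versus incorrect trials: same direction = Cue, opposite =
Action, exact ties or empty cells = unsubclassified. Chi-squared tests
are k-sample equal-proportion tests without continuity correction
(df = k - 1); degenerate tables (a state in all or no trials) are
treated as non-significant.

Controls: stimulus-label permutations (within outcome strata, so the
correct/incorrect structure is preserved), a circular per-neuron
per-trial shift (preserves autocorrelations, destroys co-activation),
and a 5 ms column-swap (preserves co-activation, destroys
autocorrelations). Both shuffles preserve per-neuron trial spike
counts exactly.

## Onset times, ordering, similarity

Onsets of coding-state intervals are taken relative to the taste event,
clipped below at 0 (left padding) and above at 1 after division by the
trial IEI. Histograms use 0.05-unit bins, linearly interpolated (100
points per gap) and smoothed with a Gaussian filter of 400-point width;
"width" is interpreted as a kernel of that many points with
`sigma = width/6`, truncated and renormalized at the window edges. The
inferred peak is the argmax of the smoothed, normalized density. The
per-trial ordering statistic restricts to trials with at least two
coding classes and requires every Quality onset to precede every Cue
onset present, and every Cue onset to precede every Action onset.

The sequence-similarity measure compares two conditions decoded by the
*same* fitted model. Per 2 ms bin and stimulus, the admissible state
labels of the condition's trials (0 = none) form a vector; the raw
similarity is the fraction of matching pairs over all cross-condition
trial pairs, averaged over stimuli, and is normalized by the control's
self-similarity. Zeros match zeros in the raw count, as the
normalization compensates. Traces are smoothed with a 150-bin Gaussian
filter of the same convention.

## The synthetic-session generator

`generate_session` draws Markov-switching firing-rate states at 2 ms
resolution and emits Bernoulli spikes (`rate x 0.002` per bin). Planted
coding states make the classification target exact: each planted state
is reachable only in trials of its preferred condition (probability 0.8
preferred / 0.2 otherwise) and only within a stated window of warped
time, where it is entered once at a uniform time and dwells
geometrically. `default_session_spec()` mirrors a typical session: 5
neurons, 200 trials, 5 states (two background, one early Quality, one
mid-trial Cue, one late Action), IEI uniform on [2.01, 3.05] s (mean
2.53 s), labels at 82% accuracy. The chain's self-transition is
calibrated so that *observed* state durations — which are truncated at
trial boundaries and planted entries — average about 577 ms; the
untruncated geometric mean is correspondingly longer (1.2 s).

What the generator does *not* emulate: refractoriness, bursting,
rate drifts, electrode artefacts, and correlated noise across neurons.
Passing recovery tests on this generator shows the pipeline is correct
under its own assumptions, not that real recordings satisfy them.

## The clustered network model

The network has 4000 excitatory (E) leaky integrate-and-fire neurons —
14 clusters of 250 plus 500 unclustered background neurons — and 994
inhibitory (I) neurons in 14 partner clusters of 71. Membrane dynamics
follow `dV/dt = -(V - V_L)/tau_m + (I_ext + I_syn)/C`, integrated by
forward Euler at `dt = 0.05` ms; a spike resets V to `V_r` for the
refractory period. Synaptic currents are exponentially filtered trains
of presynaptic impulses; an impulse increments the current by
`J_ij / tau_syn`, so the time-integral of one postsynaptic current is
exactly `J_ij` (weights in pA·ms; with `C = 1` the same numbers act as
mV·ms on the membrane).

Connectivity is random with *fixed in-degree*: each neuron draws
exactly `round(P x population size)` presynaptic partners per
population, which holds in-degrees identical across network instances
and removes in-degree disorder as a source of rate bias. Weights are
reference values `J_EE, J_EI, J_IE, J_II` times structural factors:
intra-cluster potentiation (`J_E++`, `J_I++`), E–I partner-pair
potentiation (`J_I+`), inter-cluster depression (`J_E-`, `J_I-`). Eight
clusters are randomly assigned roles (four tastes, two cues, two
actions). Taste clusters have a strongly connected 25% overlap subset
cross-wired at `J_++` to the same-quality partner's subset (S–M, Q–O);
the remaining within-taste-cluster synapses use the weaker `J_+`. Cue
and action wiring follows the published factors exactly: taste-to-cue
+85% on 60% of synapses (correct pairings), cue intracluster +5% on
60%, anti-cue inhibition +40% on 50%, cue-to-action x2.75 (correct) and
x2.60 (incorrect) on 50%, action intracluster +7% on 50%, anti-action
inhibition x3 on 50%, and action-I-to-cue-E +40% on 50%. Cue-pair
members integrate synaptic input with slower kinetics (E-type x2.3,
I-type x1.3) and action-pair members slower still (x3.30 / x3.25).
Every block mean of the resulting matrix is audited in the tests
against its closed form
`P(P_M J_M + 1 - P_M) J_factor J_reference`.

The stimulus is a double exponential whose peak equals the gain (60% or
200% of baseline external current), delivered to a random half of the
taste cluster, drawn once per network instance. The action gate ramps
linearly 0 to 1 over 0.5 s from a random onset in [1.1, 1.9] s and
withholds the *excitatory* recurrent input of action-cluster E neurons:
gating their total synaptic input would disconnect them from inhibition
and make them fire tonically on their suprathreshold baseline, so the
excitatory-only gate is the default (a `gate_mode` flag restores the
total-input variant). Silencing is a square pulse added as a percent
increase of the baseline external current of all inhibitory neurons.

### Choice of the baseline constants

The baseline biophysical constants are not uniquely determined by the
architecture, so the shipped defaults are the package's own operating
point, selected (in this order of priority) so that:

1. cue selection is reliable — the cue cluster matching the cued
   direction wins in ~97% of trials;
2. behavioural errors arise mostly *downstream* of the cue, at the
   action competition, which is what makes both Cue-coding states
   (preference stable across outcomes) and Action-coding states
   (preference flipping with outcome) observable;
3. overall accuracy is near 0.8, with delay-period silencing more
   damaging than sampling-period silencing;
4. the same-quality overlap partner co-activates with the stimulated
   taste cluster, which is what produces Quality-coding states;
5. spontaneous activity is metastable, with cluster dwell times of
   order 10^2–10^3 ms and E rates of a few Hz.

Two modelling decisions deserve emphasis. First, the cross-cluster
overlap potentiation is applied within-type (E-subset to E-subset,
I-subset to I-subset): potentiating the cross-type pairs as well makes
the partner's inhibitory overlap cancel the excitatory overlap drive,
and the partner cluster then never co-activates. Second, the network
receives a weak ongoing noise current (SD 0.8 mV/ms, redrawn every
1 ms, *shared* within each cluster's E and I populations separately,
emulating correlated afferent fluctuations). With initial-condition
randomness alone the evoked cascade is quasi-deterministic: accuracy
saturates near 1 with no incorrect and no ambiguous trials, leaving the
Cue/Action subclassification undefined and onset distributions
degenerate. Setting `noise_sd = 0` restores the fully deterministic
contract (identical seeds give bitwise identical spike trains; this
also holds with noise, whose stream is seeded).

A known limitation at this operating point: with partner inhibition
weak enough for a competitive action winner-take-all, spontaneous
switching engages mainly the strongly potentiated generic clusters —
typically 2–6 of 14 clusters express high-rate epochs in a 10 s window,
sparser than the ideal in which nearly all clusters take turns. The
taste clusters participate under stimulation instead. Strengthening
partner inhibition enriches spontaneous switching but inverts the
action competition (the winner suppresses itself more than its rival),
which is a worse failure mode.

## Behaviour scoring and in-silico experiments

Action-cluster rates are computed in 50 ms bins per neuron; a cluster
is "on" at or above 40% of its maximum rate over the whole session (an
absolute threshold is available). A trial is correct if the
cued-direction action cluster comes on in [0.5, 3] s and the other does
not, incorrect in the mirrored case, and otherwise ambiguous: a random
decision with expected accuracy 0.5 is assigned and the trial is
excluded from coding analyses. "Comes on" means an on-interval
overlapping the window; a strict-onset flag requires the onset inside
it. Cue onsets are detected with the same rule on the cue clusters.

`run_control` chains everything: simulate trials (balanced tastants,
random gate onsets), score behaviour, sample one E neuron per cluster
(avoiding sub-2 Hz neurons when possible) into a 14-neuron session
whose decision event is the scored action onset, fit and select an
HMM, decode, classify (ambiguous trials excluded), and pool warped
onsets. `run_silencing_grid` crosses silencing conditions (sampling:
100% for 0.5 s centred at 0.25 s; delay: 100% for 2.5 s centred at
1.75 s) with stimulus segments and runs repeated-measures ANOVAs
(computed from the standard sums-of-squares decomposition with networks
as subjects — validated in the tests against `stats::aov` — with
Bonferroni-corrected paired post-hocs). `run_sliding_pulse` slides a
250 ms pulse along the trial at 25% and 100% strength.
`run_fig7_protocol` reuses one network's control initial conditions
across six pulse conditions ({weak, strong} x {beginning, cue-onset,
mid-trial}), fits a single HMM to all conditions' trials so state
labels are comparable, and compares each condition's decoded sequences
with control via the normalized similarity trace plus an Action-coding
correct/incorrect/none accounting.

## Problem sizes used by the shipped tests and acceptance script

The published protocol is 10 networks x 100 trials with a state search
up to M = 50; the package defaults keep those values configurable. The
shipped test suite and `scripts/acceptance.R` run the same protocols at
desk scale, which the package treats as its reference problem sizes: 2
networks x 80 control trials at gain 200% (coarse state grid 2, 5, 8,
11), 2 networks x 40 trials per silencing condition, 10-seed recovery
runs on 200-trial synthetic sessions with 1.0–1.5 s IEIs, and a
miniature (1 network x 4 trials x 7 conditions) instantiation of the
shared-initial-condition silencing protocol. At these sizes the
qualitative results — the Quality-to-Cue-to-Action onset progression,
accuracy near 0.8, and the silencing ordering — reproduce; exact
reproduction of the published full-scale figures requires the
full-scale settings and several hours of compute.

## Known limitations

- The HMM's one-spike-per-bin symbolization discards coincident spikes;
  at 2 ms bins and cortical rates the loss is small but nonzero.
- Classification power depends on incorrect-trial counts; sessions with
  one-sided errors leave Decision states unsubclassified, as in the
  experimental procedure.
- The network is current-based, delay-free and plasticity-free; its
  biophysical constants are an operating point, not a fit to data.
- Quality-coding states hinge on sampled neurons landing in overlap
  subsets and on partner co-activation; they are the rarest class, as
  in the recordings.
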