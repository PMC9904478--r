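# spikestates

Metastable-state analysis of ensemble spike trains, and a clustered
spiking-network model of taste-guided decision-making.

## What this package is for

Cortical ensembles often move through sequences of quasi-stationary
firing-rate patterns — *metastable states* — with abrupt transitions at
variable times. In a four-taste, two-alternative choice task (sucrose
and quinine cue a left response, maltose and octaacetate a right one,
deliberately crossing taste quality with response side), such states
can encode the sensory, cognitive and motor variables of the task in
sequence. `spikestates` provides, for researchers analyzing ensemble
recordings or modelling them:

- **A discrete-symbol spike-train HMM**: 2 ms symbolization (one
  symbol per bin: the firing neuron's index or a null symbol),
  multi-start Baum–Welch fitting, state-number selection by
  `BIC = -2LL + [M(M-1) + MN] ln B`, and posterior decoding with an
  admissibility criterion (posterior ≥ 0.8 for ≥ 50 ms).
- **Coding-state classification**: per-state occurrence tables by
  condition, 4-way chi-squared tests at the Sidak-corrected level
  `1 - 0.95^(1/N_d)`, Marascuilo post-hoc comparisons, the
  TasteID / Quality / Decision / Dual / Noncoding pipeline, and the
  Cue-vs-Action subclassification from correct vs incorrect trials.
- **Temporal analysis**: onset times warped by the trial's
  taste-to-decision interval, smoothed onset distributions, a per-trial
  ordering statistic, and a time-resolved state-sequence similarity
  `rho` between perturbed and control conditions.
- **Surrogate controls**: circular spike-train shifts, 5 ms column
  swaps, and stimulus-label permutations.
- **A synthetic-session generator** with planted, condition-gated
  coding states, so every analysis stage is testable against ground
  truth.
- **A clustered E/I spiking network** (4000 excitatory + 994 inhibitory
  LIF neurons in 14 partner cluster pairs, fixed in-degree random
  connectivity) that performs the task via a taste → cue → action
  cascade, with taste-cluster overlaps, an action gate, simulated
  optogenetic silencing, behaviour scoring, and repeated-measures
  ANOVA comparisons.

## A worked example

Generate a synthetic session with a planted early Quality state, a
mid-trial Cue state and a late Action state, then recover them:

```r
library(spikestates)

spec <- default_session_spec()        # 5 neurons, 200 trials
gs   <- generate_session(spec, seed = 42)
ps   <- preprocess_session(gs$session)  # 2 Hz / 3-neuron screening
sy   <- symbolize(ps, seed = 1)         # 2 ms symbol sequences

model <- select_model(sy, M_range = 2:6, n_init = 10, seed = 7)
model
#> <hmm_model> M = 5 states, N = 5 neurons, LL = -89757.36, BIC = 180077.68

dec <- decode(model, sy)
dec
#> <decoded_states> 200 trials, 754 admissible intervals, M = 5

cl <- classify_states(dec, session_trials(gs$session))
coding_class(cl)
#> [1] "Quality" "Cue"     NA        "Action"  NA

on <- warp_onsets(dec, session_trials(gs$session), coding_class(cl))
aggregate(onset ~ class, on, mean)
#>     class     onset
#> 1  Action 0.7920219
#> 2     Cue 0.5110069
#> 3 Quality 0.2007422
ordering_fraction(on)$fraction
#> [1] 0.7702703
```

The three planted classes are recovered with their temporal order
(Quality ≈ 0.20, Cue ≈ 0.51, Action ≈ 0.79 in warped units, where 0 is
the taste event and 1 the decision), and 77% of trials containing two
or more coding classes show the proper Quality → Cue → Action
ordering.

On the model side:

```r
net <- build_network(network_params(), seed = 1)   # one instance
trial <- simulate_trial(net, neuron_params(),
                        stimulus = stimulus_spec(gain = 200),
                        taste = "S", gate = gate_spec(1.5), seed = 11)
trial
#> <spike_data> 74121 spikes over 3 s (taste S)
```

`run_control()`, `run_silencing_grid()`, `run_sliding_pulse()` and
`run_fig7_protocol()` chain building, simulation, scoring, sampling,
HMM fitting and classification into the full in-silico experiments.

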