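# myodecode

Myoelectric motion decoding with muscle synergies and extreme learning
machines.

`myodecode` is a simulation and analysis pipeline for real-time intent
decoding from multi-channel surface electromyography (EMG). It is aimed
at researchers in myoelectric control who want to compare the two
standard feature-extraction routes — per-channel time-domain features
versus muscle-synergy activations — under a single decoder and a
reproducible, fully synthetic testbed: the package generates its own
labeled EMG sessions with planted synergy structure, so every stage is
testable end to end without any recordings.

## What it implements

**Session model.** A session is a `p × q` multi-channel recording
`X ∈ R^{p×q}` (default p = 7 channels at 1 kHz) organized into labeled
trials: 5 motion classes plus rest, 3 s trials with 2 s rest, 10
repetitions per class for training and 20 for testing. The synthetic
generator plants a non-negative synergy basis `A` (unit-norm columns)
and per-class activation time courses, adds per-repetition amplitude
jitter and Gaussian noise, and lays the trials out per protocol.

**Preprocessing.** Full-wave rectification followed by a 4th-order
Butterworth low-pass at 10 Hz gives the envelope; zero-phase
(forward–backward) for offline work, single-pass causal for the online
simulator.

**Features.** A 100-sample sliding window advanced by 10 samples (90
overlap, one decoder output per 10 ms) yields either

- *EMG features*: per channel, MAV = (1/N) Σ|xₙ| and the uncentered
  variance VAR = (1/(N−1)) Σ xₙ², i.e. dimension 2p = 14; or
- *synergy features*: non-negative matrix factorization `X ≈ A Y`
  fitted on the training envelopes by alternating non-negative least
  squares; the number of synergies is the smallest k whose cumulative
  explained variance reaches 90 % with a per-step gain below 5 %.
  Online, activations are decoded as `Y = pinv(A) X` (the
  least-squares inverse of the rectangular basis); dimension k
  (typically 4).

**Classifier.** A from-scratch extreme learning machine: a single
hidden layer of random frozen neurons (triangular basis activation
`max(1 − |v|, 0)` on z-scored inputs), with the output weights solved
in closed form as the ridge regression
`w* = (HᵀH + λI)⁻¹ Hᵀ o` against one-hot class targets. Hidden-layer
size can be selected by stratified 2-fold cross-validation.

**Online simulation.** The testing session is streamed causally; each
10 ms tick classifies the trailing window and drives a virtual arm
whose pose changes follow the minimum-jerk profile
`s(t) = 10t³ − 15t⁴ + 6t⁵`. A trial completes when the commanded pose
is reached and held 0.5 s. Reported metrics: offline accuracy,
per-class online accuracy over completed trials, motion selection and
completion times, exponential learning trend `y = a·e^{−bx} + c`,
trial-to-trial variability (mean per-channel, per-timepoint population
SD after resampling each repetition to 200 samples), and row-normalized
confusion matrices.

## Worked example

```r
library(myodecode)

cfg <- run_config(synth = synth_config(seed = 1),
                  pathway = "synergy", hidden_grid = 500L)
res <- run_experiment(cfg)
res
#> <experiment_result> pathway=synergy, feature dim 4, 4 synergies
#>   offline accuracy: 99.00 % (n_hidden = 500)
#> <performance_report> online accuracy 100.00 %, completion rate 100.0 %
#>   mean selection time 0.000 s, mean completion time 1.530 s
```

Reading the output: the explained-variance criteria picked 4 synergies
(the number planted by the generator), the decoder classifies 99 % of
held-out training windows correctly, and in the simulated online phase
every commanded trial was completed — the arm reached and held the
right pose — with the decoder emitting the commanded class on
essentially every tick between movement onset and completion. The mean
completion time (~1.5 s) is the 1 s minimum-jerk transition plus the
0.5 s hold, reached with almost no decoder hesitation. Per-class
breakdowns, confusion matrices and learning-trend fits live in
`res$online`.

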