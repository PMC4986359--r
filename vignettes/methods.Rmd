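---
title: "Decoding upper-limb motion intent from EMG: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding upper-limb motion intent from EMG: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`myodecode` implements a complete myoelectric intent-decoding study on
synthetic surface-EMG data: two feature pathways (per-channel
time-domain features versus muscle-synergy activations) feeding one
classifier (an extreme learning machine), evaluated both offline and in
a simulated real-time loop. This vignette is the package's account of
the underlying science and of the choices made where the methods leave
room.

## The decoding problem

A session records `p` EMG channels at rate `f_s` while a subject
performs discrete motion classes (here five upper-limb motions plus
rest). The decoder must map a short trailing window of muscle activity
to the intended class, every 10 ms, reliably enough to drive an
assistive device. Two families of inputs are standard:

* **EMG features** describe each channel separately. Per 100 ms window
  and channel we compute the mean absolute value,
  $\mathrm{MAV} = \frac{1}{N}\sum_n |x_n|$, and the uncentered variance
  $\mathrm{VAR} = \frac{1}{N-1}\sum_n x_n^2$. Note VAR as used in this
  literature is a power measure — a mean square over `N − 1` without
  mean subtraction — not the statistical variance; `emg_var()`
  implements exactly that form and is named to avoid colliding with
  `stats::var`.
* **Synergy features** exploit the observation that the nervous system
  coordinates muscles through a small set of co-activation patterns.
  Non-negative matrix factorization decomposes the envelope matrix as
  $X = AY + E$ with $A \ge 0$ the `p × k` basis of synergies and
  $Y \ge 0$ the activation coefficients; the k activation coefficients
  replace the 2p channel features.

## Synthetic sessions: what they emulate, and what they do not

No recordings ship with the package; the generator (`synth_config()`,
`make_ground_truth()`, `generate_session()`) produces sessions with a
known planted structure:

* a non-negative basis of `n_true_synergies = 4` unit-norm columns,
  each loading dominantly on its own subset of channels (sparse
  co-activation, as physiological synergies do);
* per-class synergy weight vectors spread in the non-negative orthant
  by a `separation` parameter (0 makes every motion class identical —
  a useful degenerate control — and large values approach orthogonal
  class codes);
* per-synergy activation time courses shaped as a tapered-cosine
  (Tukey) plateau over the 3 s trial — rise out of rest, hold, release,
  matching a protocol in which the subject assumes and holds a pose —
  mixed (0.55/0.45) with a narrower raised-cosine bump staggered across
  the trial per synergy. The stagger makes the planted activation
  genuinely 4-dimensional in time; without it the session would be a
  set of rescaled copies of one time course and the factorization
  could explain it with fewer synergies than were planted;
* per-repetition amplitude scale `1 + 0.1·z` and additive Gaussian
  noise (`noise_sd = 0.02` envelope units against plateau activations
  of order 0.5–1) on the raw signed signal, so that rectification and
  filtering remain meaningful;
* the session protocol: 3 s trials, 2 s inter-trial rest, 10
  repetitions of each of the 6 classes (rest is its own labeled class,
  since the online decoder must emit "rest") for training, and 20
  repetitions of each of the 5 motion classes in seeded random order
  for testing, with rest present as inter-trial baseline.

Amplitudes are in arbitrary units: the pipeline is scale-covariant
(features are z-scored before the classifier, the NMF basis is
normalized), so no stage depends on a physical calibration.

What the generator deliberately does **not** model: motion artifacts,
electrode shift, fatigue and other nonstationarities; co-contraction;
and — most importantly — the human in the loop. In a real online
session the subject reacts to visual feedback and re-shapes their
muscle activity; here the testing streams are open-loop draws from the
same distribution as training. Consequently passing tests demonstrate
the correctness and internal consistency of the pipeline, not its
performance on real EMG; quantities that hinge on human adaptation
(learning trends, feedback-driven variability differences between
pathways) come out flat/identical by construction.

## Preprocessing

Envelopes are obtained by full-wave rectification followed by a
low-pass at 10 Hz. The filter family and order are a choice:
a 4th-order Butterworth, the common EMG envelope filter
(maximally flat passband). Training data are filtered zero-phase
(forward–backward) by default; the online simulator always filters
causally, because a real-time loop cannot look ahead. The
`training_filter` switch lets the training side mirror the causal
filter exactly if desired. Filter undershoot can produce small negative
values; these are clipped to zero so the result is a valid input for
the non-negative factorization.

## Synergy extraction

`nmf_fit()` minimizes $\|X - AY\|_F^2$ by alternating non-negative
least squares, each half-step solved to optimality by a grouped
active-set solver (`ridge = 1e-12` on the normal equations for
conditioning), so the objective is non-increasing by construction —
a property the tests assert on every iteration. Basis columns are
renormalized to unit length each sweep (a pure reparameterization).

The number of synergies is chosen on the cumulative explained-variance
profile $EV(k) = 1 - \|X - AY\|_F^2 / \|X\|_F^2$: the smallest k with
`EV(k) ≥ 0.90` **and** `EV(k+1) − EV(k) < 0.05` (the profile has
flattened; `EV(p+1)` counts as 1). Two conventions needed fixing:

* *Uncentered total sum of squares.* NMF has no intercept and
  envelopes are non-negative, so `SST = ‖X‖²_F` is the natural
  denominator (the muscle-synergy literature's convention); a
  mean-centered alternative is available via `centered = TRUE`.
* *Slope criterion.* "Change in slope below 5 %" is formalized as the
  successive difference `EV(k+1) − EV(k) < 0.05`.

Each k is warm-started from the `k − 1` solution (in addition to a
fresh random start, keeping the better), which guarantees a
non-decreasing profile. The factorization is fit on the concatenated
training *motion* trials only — rest carries no synergy information —
with an `include_rest` switch. Because the envelope is band-limited at
10 Hz, the fit subsamples to an effective 100 Hz (`decimation = 10`);
this loses nothing while cutting cost tenfold.

Online, coefficients are decoded as `pinv(A) x` — the Moore–Penrose
pseudoinverse is the only standard reading of "A⁻¹" for a rectangular
basis, and equals the least-squares decoder used throughout real-time
linear decoding. Decoded coefficients may be slightly negative and are
deliberately *not* clipped: the online map is a plain linear operator.
Per window, the synergy feature is the mean coefficient vector (by
linearity, the projection of the window-mean envelope) — the natural
MAV analog for non-negative activations; a per-sample `passthrough`
mode is provided since the windowing of synergy coefficients ahead of
classification admits either reading.

## The extreme learning machine

The ELM is a single-hidden-layer network whose hidden parameters are
random and frozen; only the linear output layer is learned, in closed
form. With activation matrix `H` (`n × N`) and one-hot targets `o`,
the output weights solve the ridge problem
$w^* = \arg\min \|Hw - o\|^2 + \lambda \|w\|^2
     = (H^\top H + \lambda I)^{-1} H^\top o.$
The equivalent `C`-parameterized constrained form is the same problem
with `λ = 1/C`, so only the ridge form is implemented. Design points:

* Hidden weights and biases are i.i.d. uniform on `[−1, 1]`, the
  convention of the original ELM literature; the default activation is
  the triangular basis `max(1 − |w·y + b|, 0)` (affine additive nodes;
  RBF and sigmoid are alternatives).
* The triangle has support only for pre-activations in `(−1, 1)`, so
  inputs are z-scored with training statistics stored in the model —
  raw envelope scales would saturate every neuron to zero.
* The solve uses Cholesky on `HᵀH + λI` with a pseudoinverse fallback
  for singular systems; never an explicit inverse. `λ` defaults to
  `1e-3` (the value is not critical in the tested regimes and is a
  config knob).
* Prediction is argmax over the m output nodes; ties break to the
  lowest class index, deterministically.
* Hidden-layer size can be chosen by stratified 2-fold
  cross-validation over a grid defaulting to
  {500, 1000, 2000, 3500, 5000}, the range typical for this decoding
  problem.

## The simulated online phase

The testing session is filtered causally and streamed: a 100-sample
ring buffer advances 10 samples per tick; each tick extracts features
(either pathway), predicts a class, and feeds the virtual-arm state
machine. Choices where the loop's mechanics were open:

* **Debouncing** (`debounce = 5` ticks, i.e. 50 ms): a class must
  persist to (re)target the arm, preventing chattering; `debounce = 1`
  reproduces raw per-tick behavior.
* **Transition duration** 1.0 s per pose change, following the
  minimum-jerk profile `10t³ − 15t⁴ + 6t⁵`; a new sustained command
  mid-flight redirects the arm from its current fractional position
  (progress resets, duration fixed).
* **Movement onset** is the first tick predicting non-rest;
  *selection time* is the first tick predicting the target, minus
  onset; *completion* requires reaching the commanded pose and holding
  it 0.5 s, and *completion time* is measured from onset.
* **Timeout** 30 s (a finite simulation cannot wait forever); in
  practice a trial's stream ends at the next trial's start, and
  unfinished trials are recorded as not completed and excluded from
  completion-time and online-accuracy averages, which are defined over
  successfully completed trials only.

## Performance metrics

Offline accuracy is the correct-window percentage on a held-out split
of the training data. The split is stratified **by trial**, not by
window: adjacent windows share 90 of 100 samples, and splitting windows
at random would leak nearly-identical feature vectors across the split,
inflating accuracy (measurably so in the degenerate `separation = 0`
control). The split fraction defaults to 50/50.

Online accuracy per class is the mean over completed trials of the
per-trial fraction of correct decoder outputs between onset and
completion, ×100. A class with no completed trial is reported missing
(`NA`), never zero. The learning trend fits `y = a·e^{−bx} + c` to
per-repetition completion times by bounded multi-start
Levenberg–Marquardt (`b ∈ [−5, 5]`, three starts), flagging
unidentifiable fits on near-constant data instead of trusting `b`;
with this parameterization positive `b` means improvement, and the raw
fitted value is stored (the sign convention used when tabulating such
values varies, so both readings are documented rather than guessed).
Variability resamples each repetition's envelope to 200 points on
normalized time (linear interpolation by default) and averages the
population standard deviation (divisor `nRep`, as defined) over
channels and time points. Confusion matrices are row-normalized to 100
with actual classes as rows.

## Problem sizes and numerical checks

The package's own test battery runs the full protocol scale — 7
channels at 1 kHz, 60 training trials (about 17 500 windows of
dimension 14), 100 testing trials — with a 500-neuron ELM, and
desk-scale variants (5 channels at 200 Hz) for the per-module tests;
these sizes keep a complete two-pathway run in the tens of seconds on
one core while exercising every code path at realistic dimensions.
Oracles used in the tests are independent of the implementation:
brute-force loops for MAV/VAR, dense normal-equation solves for the
ELM weights and the online projection, a reference active-set NNLS
solver for the factorization's inner step, and hand-derived values for
the metric formulas. Degenerate inputs are handled explicitly:
rank-deficient normal equations fall back to a pseudoinverse (logged),
dead NMF columns are reseeded, near-constant learning-trend data are
flagged unidentifiable, and windows shorter than the buffer are
skipped with a warning.

## Known limitations

* Open-loop testing: no model of user adaptation or feedback-driven
  strategy change, so cross-pathway differences that arise from the
  human side in closed loop are absent by design.
* The synthetic noise is white and Gaussian on the raw signal;
  real EMG interference (powerline, motion artifact, crosstalk) is not
  modeled.
* NMF is fit per session; cross-day or cross-subject synergy transfer
  is out of scope.
* The ELM uses a single hidden layer with dense random projections;
  kernel and sequential variants are not implemented.
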