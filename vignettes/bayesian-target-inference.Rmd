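---
title: "Bayesian target inference from noisy multi-class feedback: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian target inference from noisy multi-class feedback: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(navbci)
```

This vignette is the package's account of its model and of every
numerical and design choice that was genuinely open. It states no
empirical result beyond what the test suite and `scripts/acceptance.R`
themselves compute.

## Setting

A virtual robot navigates an `n × m` grid of cells with 4-connectivity
(no diagonal moves), aiming to reach and *identify* a target cell known
only to the observing user. The robot knows the map — shortest paths are
assumed available — but not the target. Feedback arrives only as the
output of a noisy classifier of the user's event-locked EEG responses:
each movement is labelled `TT` (towards target), `TR` (target reached),
`FA` (further away) or `SO` (stepped off), and each identification action
is labelled `CTI` (correct) or `FTI` (false). Because a 4-connected move
always changes the Manhattan distance to any cell by exactly 1, the four
movement classes are exhaustive and mutually exclusive for every
(move, hypothesised target) pair.

Runs start with the target uniform over all cells and the robot uniform
over all cells at Manhattan distance ≥ 2 from it, with no maximum
distance. The start distribution beyond the minimum-distance constraint
is not dictated by the task description; uniform over the eligible set is
the assumption made here.

## Posterior inference

The robot maintains `P(T_{i,j})`, the probability that cell `(i, j)` is
the target, initialised at `1/(n·m)`. After observing classifier output
`O_t` for a move, each cell's mass is multiplied by the likelihood of
that output under the *counterfactual* class the move would have had if
that cell were the target, divided by the output's marginal probability,
and the field is renormalised:

$$P(T^{t+1}_{i,j}) \propto P_A(O_t \mid T_{i,j})\, P(T^t_{i,j}),
\qquad
P_A(O_t \mid T_{i,j}) = A[\,O_t,\ s(i,j)\,]$$

where `A[o, s] = P(output o | true class s)` is the confusion-matrix
observation model, column-stochastic with rows indexing outputs, and
`s(i, j)` is the counterfactual class. The marginal divisor
`P(O_t)` (row sum of `A` over its total) is constant across cells and
cancels in the renormalisation; the implementation applies it anyway for
fidelity to the textbook form, and a test asserts the cancellation
algebraically. Identification actions judged false trigger a *downdate*
with the 2×2 identification matrix: the identified cell's counterfactual
class is `CTI`, every other cell's is `FTI`.

Indexing convention: `A[observation, state]`. The available prose
descriptions of where the value is read from (row vs column) are not
mutually consistent; only `P(O_t | S)` enters the update, so the
column-stochastic-in-the-state convention is adopted and documented on
`likelihood_matrix()`.

### Likelihood floor

Leave-one-out contingency tables can contain zero cells; a hard zero
likelihood would permanently annihilate the true target's posterior after
a single unlucky output. Every constructed matrix is therefore floored at
`1e-6` and re-normalised (configurable; 0 disables). How zero cells were
handled originally is not stated anywhere; the floor is this package's
choice.

### Identification decision

`stringency ∈ [0.1, 0.9]` sets two thresholds:

- lower = `stringency`, applied when the latest output is `TR`;
- upper = `(stringency + 0.1) / (stringency + 0.2)`, applied otherwise,
  and used alone by the binary-classification variant.

This functional form is a reconstruction anchored by three fixed points:
at stringency 0.1 a `TR` output identifies once the current cell holds
more than a 10% chance; without `TR` the cell must be more than twice as
likely as all other cells combined (2/3); and the binary variant's
threshold is printed exactly as the upper formula. Inequalities are
strict. The decision runs only after movement updates; after a
deselection the next action is always a movement.

### Action selection

The robot steps along a shortest path towards the posterior argmax, ties
broken uniformly at random. When the argmax is the robot's own cell but
the thresholds are unmet, it steps towards the most probable *other*
cell: staying put would deadlock (no new movement evidence would ever
arrive), and moving off the candidate generates exactly the
discriminative `SO`/`TT` evidence the posterior needs. This rule is this
package's resolution of a case the source description leaves open.

## Baselines and variants

**React** trusts the latest output completely: `TR` → identify; `FA`/`SO`
→ move back (undoing the error); `TT` → random neighbour excluding the
previous cell for one action only. At a 1-D end-cell whose only
neighbour *is* the previous cell the exclusion is waived — the robot
must move somewhere; this waiver is the minimal consistent rule. After
an identification is undone by `FTI`, all neighbours are eligible again
and the one-step memory (`previous`) is left unchanged.

**Random** identifies its current cell with probability `1/(n·m)` on
*every* action — including the first — and otherwise moves to a uniform
random neighbour; its runs end at the first identification with no
identification classification. The classifier-driven strategies instead
open with a uniformly random movement, since they cannot act on feedback
before any exists.

**Variants** of the Bayesian system: `no_tic` ends the run at the first
identification action (no deselection possible); `binary` collapses the
movement model to 2×2 correct/error (pooling `TT`+`TR` and `FA`+`SO`)
and uses the upper threshold alone, since no `TR`-specific output
exists. When a probability matrix rather than a counts table must be
collapsed, columns within a pooled group are averaged (each true class
weighted equally) and rows summed.

## Metrics and aggregation

- **PTCI** = 100 × (correct runs)/(runs). Capped runs count as
  incorrect.
- **MNS** = mean over correct runs of movement steps ÷ initial
  shortest-path distance. Steps count movement actions only;
  identification actions (including undone ones) are excluded — the
  definition here, since "steps" is not defined more precisely in the
  source. With no correct runs the metric is reported as missing, never
  zero.

Headline values aggregate per participant first, then mean ± s.d. across
participants; `aggregate_sweep()` also emits the pooled per-run MNS
(`mns_pooled`) matching distribution-style summaries that combine all
participants.

A step cap of `50·n·m` movement actions terminates episodes that cannot
converge (e.g. chance-level matrices at high stringency); capped runs are
flagged and scored incorrect.

## Observation sampling and virtual participants

In simulation, drawing a classifier output for a true class replaces
retrieving a held-out EEG trial of that class and classifying it.  A
`participant_profile` carries two matrix pairs: *sampler* matrices (the
true test-set confusion behaviour generating outputs) and *assumed*
matrices (the robot's model, in reality a leave-one-out estimate from
training data). `synth_participant()` draws per-class diagonal
accuracies uniformly from configurable ranges (defaults: movement
0.55–0.85, identification 0.65–0.90, chosen once as realistic
single-trial ERP classification performance) and spreads the residual
over off-diagonals by a symmetric Dirichlet draw. `mismatch` blends the
assumed matrices with an independent draw to emulate the training-vs-test
discrepancy; it defaults to 0 (robot's model exact), which is also the
setting used throughout the tests.

## The SWLDA layer

Epoch preprocessing: zero-phase 4th-order Butterworth band-pass, 64 Hz
resampling on the event-locked `1/64 s` grid, per-channel baseline
correction to the mean of [−200, 0) ms, and concatenation of the
half-open [200, 700) ms window — 32 samples per channel, 256 features
over 8 channels. The half-open endpoint convention is fixed so feature
counts are deterministic. Stage 1 (correct-vs-error) and the
identification classifier use 1–10 Hz; stage 2 subclassifiers use
1–32 Hz.

The band-pass is applied as the squared magnitude response of the
designed Butterworth filter in the frequency domain (with channel-mean
removal and odd-reflection padding), which is exactly the zero-phase
forward–backward response. The direct IIR recursion is numerically
ill-conditioned for a 1 Hz high-pass edge at 500 Hz (poles very near the
unit circle, producing edge transients and linearity errors orders of
magnitude above machine precision); the FFT route is linear to ~1e−15
and makes a constant epoch map to exactly zero features.

Classification is stepwise linear discriminant analysis: least-squares
regression of the 0/1 class indicator, with forward entry of the most
significant candidate (partial F-test, p < 0.05), backward removal of
included features whose p exceeds 0.10, and at most 60 features. These
three thresholds are standard SWLDA practice for ERP work — the original
values are not printed in the available text — and all are configurable.
The movement classifier is a 2-stage tree (correct-vs-error on 1–10 Hz
features, then `TT` vs `TR` or `FA` vs `SO` on 1–32 Hz features);
stage-2 models are trained on the epochs whose *true* classes belong to
the branch, which is the assumption made here. `loo_likelihood()`
refits the tree once per held-out epoch and accumulates the
predicted-by-actual counts.

## Synthetic ERP generator

`erp_templates()` encodes the qualitative grand-average structure:
erroneous actions evoke larger peaks than correct ones, with
class-specific amplitudes (TT 2, TR 4, FA 5.5, SO 8 µV; CTI 3, FTI 7 µV)
and latencies (320–450 ms), scaled by a fronto-central topography over
the Fz, Cz, Oz, Pz, C3, C4, PO7, PO8 montage. Epochs are the class
template times a trial-level amplitude jitter (s.d. 0.1, the realistic
default) plus per-channel pink noise (spectral exponent 1, s.d. 2 µV by
default).

What the generator does *not* emulate: inter-channel noise correlation,
latency jitter, eye/muscle artefacts, non-stationarity across blocks and
overlapping responses from consecutive actions. Tests that pass on this
synthetic data therefore demonstrate the correctness of the pipeline and
its qualitative behaviour (separable classes are recovered; permuted
labels yield chance), not expected real-EEG accuracy levels.

Two points about the test conditions deserve note:

- *Separable ("high-SNR") condition*: tests of near-perfect recovery use
  noise s.d. 0.25 µV and amplitude jitter 0.05. At the default jitter of
  0.1 the class amplitude distributions genuinely overlap (an 8 µV `SO`
  trial jittered down meets a 4 µV `TR` trial jittered up), so perfect
  separability — the premise of those checks — would not hold by
  construction.
- *Permutation null*: leave-one-out classification of label-shuffled
  epochs is checked one-sidedly (no diagonal above chance + 3 s.e.).
  LOO under permuted labels is systematically pessimistic — the held-out
  trial's class is underrepresented in its training fold, and with a
  near-null feature set the majority-class tilt can push a diagonal far
  *below* chance — so a symmetric band around chance is the wrong null
  expectation.

## Problem sizes used by the suite

The test suite and acceptance script choose sizes that exercise the
study conditions while keeping runs reproducible on a single CPU: the
Random benchmarks and the stringency sweep use the study's 8 virtual
participants × 1000 runs per condition; oracle-equivalence checks use
1000 random instances on grids up to 6×6 at 1e−12 agreement;
leave-one-out checks use 12–14 epochs per class. The perfect-feedback
limits use 200 runs per grid/stringency.

## Known limitations

- Observations are conditionally independent given the true class;
  real consecutive EEG trials are not perfectly so.
- The soft-observation hook (probability-vector outputs forming weighted
  likelihood columns) is implemented but no calibration machinery is
  provided.
- Non-uniform initial posteriors are accepted as inputs but never
  learned.
- The SWLDA layer performs no artefact rejection; the synthetic
  generator produces artefact-free epochs.
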